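#' Read and validate an order-level phylogeny from newick text
#'
#' Parses a rooted, possibly polytomous newick tree whose tips are insect
#' order names. Branch lengths are tolerated and ignored by all downstream
#' node-count computations. Validation goes beyond the parser: unbalanced
#' parentheses, empty input, empty tip labels and duplicated tip labels are
#' reported with the offending position or label.
#'
#' @param x A newick string ending in ";", or the path of a file whose first
#'   line holds one.
#' @return An object of class \code{"phylo"} (see \pkg{ape}).
#' @examples
#' tr <- read_order_tree("((Coleoptera,Diptera),Odonata);")
#' tr$tip.label
#' @export
read_order_tree <- function(x) {
  if (length(x) != 1L || !is.character(x)) {
    stop("'x' must be a single newick string or file path", call. = FALSE)
  }
  text <- if (!grepl("\\(", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    x
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick string", call. = FALSE)
  if (!endsWith(text, ";")) {
    stop("newick string must end in ';' (got '",
         substr(text, nchar(text), nchar(text)), "')", call. = FALSE)
  }
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("unbalanced parenthesis: unmatched ')' at position ", i,
             call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop("unbalanced parenthesis: ", depth, " '(' never closed", call. = FALSE)
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("newick parse failed", call. = FALSE)
  tips <- tree$tip.label
  if (any(!nzchar(tips))) stop("empty tip label in tree", call. = FALSE)
  dup <- unique(tips[duplicated(tips)])
  if (length(dup)) {
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  tree
}

#' Root distances (node-count tip depths) of every order in a tree
#'
#' The root distance (RD) of a tip is the number of internal nodes on the
#' path from the root to that tip, counting the root itself under the default
#' convention, so the tips of a star tree have RD 1. The alternative
#' \code{"edge-count"} convention excludes the root (star-tree tips get 0);
#' the two differ by exactly 1 for every tip, so MRD differences and
#' latitudinal MRD slopes are identical under either. Branch lengths play no
#' role.
#'
#' @param tree A \code{"phylo"} object (see [read_order_tree()]).
#' @param convention \code{"root-inclusive"} (default) or \code{"edge-count"}.
#' @return A named integer vector, one RD per tip label.
#' @examples
#' root_distances(read_order_tree("((A,B),C);"))  # A 2, B 2, C 1
#' @export
root_distances <- function(tree, convention = c("root-inclusive", "edge-count")) {
  convention <- match.arg(convention)
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object", call. = FALSE)
  ntip <- length(tree$tip.label)
  if (ntip < 1L) stop("tree has no tips", call. = FALSE)
  nnode <- tree$Nnode
  parent <- integer(ntip + nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  # edges-on-path count: walk each tip up to the root; equals the number of
  # internal nodes on the path with the root included
  rd <- integer(ntip)
  for (tip in seq_len(ntip)) {
    d <- 0L
    node <- tip
    while (node != root) {
      node <- parent[node]
      d <- d + 1L
      if (d > ntip + nnode) stop("cycle detected in tree edges", call. = FALSE)
    }
    rd[tip] <- d
  }
  if (convention == "edge-count") rd <- rd - 1L
  names(rd) <- tree$tip.label
  rd
}

#' The default geohistorical clade-origin table
#'
#' Six species-rich insect orders with their approximate origination ages
#' (Ma before present) and the thermal class of the geohistorical window they
#' arose in: Late Carboniferous--Early Permian (320--274 Ma, "cold") versus
#' Triassic--Jurassic (250--145 Ma, "warm"). The class column is derived from
#' the age windows, never stored independently.
#'
#' @return A data.frame with columns \code{order}, \code{age_ma}, \code{origin}.
#' @export
clade_origin_table <- function() {
  tab <- data.frame(
    order = c("Hemiptera", "Coleoptera", "Hymenoptera",
              "Orthoptera", "Diptera", "Lepidoptera"),
    age_ma = c(310, 282, 250, 215, 170, 156),
    stringsAsFactors = FALSE
  )
  tab$origin <- thermal_class_from_age(tab$age_ma)
  tab
}

thermal_class_from_age <- function(age_ma) {
  ifelse(age_ma >= 274 & age_ma <= 320, "cold",
         ifelse(age_ma >= 145 & age_ma <= 250, "warm", "unclassified"))
}

#' Classify orders into warm/cold geohistorical origin classes
#'
#' @param order Character vector of order names.
#' @param table A clade-origin table (default [clade_origin_table()]).
#' @return Character vector in \{"warm", "cold", "unclassified"\}.
#' @examples
#' classify_thermal_origin(c("Hemiptera", "Lepidoptera", "Odonata"))
#' @export
classify_thermal_origin <- function(order, table = clade_origin_table()) {
  stopifnot(is.character(order))
  m <- match(order, table$order)
  out <- ifelse(is.na(m), "unclassified", table$origin[m])
  out[is.na(out)] <- "unclassified"
  out
}

#' Construct an assemblage (one reserve's species records)
#'
#' @param reserve_id Scalar reserve identifier.
#' @param species Character vector of species names, unique within the reserve.
#' @param order Character vector of order names, same length.
#' @param affinity Optional character vector of biogeographic affinities in
#'   \{"Oriental", "Palearctic", "widespread"\}.
#' @return A data.frame of class \code{"assemblage"}.
#' @export
assemblage <- function(reserve_id, species, order, affinity = NULL) {
  species <- as.character(species)
  order <- as.character(order)
  if (length(species) != length(order)) {
    stop("'species' and 'order' lengths differ", call. = FALSE)
  }
  dup <- unique(species[duplicated(species)])
  if (length(dup)) {
    stop("duplicate species within reserve '", reserve_id, "': ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  if (length(species) && any(!nzchar(order))) {
    stop("empty order name in reserve '", reserve_id, "'", call. = FALSE)
  }
  out <- data.frame(reserve_id = rep(as.character(reserve_id), length(species)),
                    species = species, order = order,
                    stringsAsFactors = FALSE)
  if (!is.null(affinity)) {
    bad <- setdiff(unique(affinity), c("Oriental", "Palearctic", "widespread", NA))
    if (length(bad)) {
      stop("unknown affinity value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    out$affinity <- as.character(affinity)
  }
  class(out) <- c("assemblage", "data.frame")
  out
}

#' Mean root distance of an assemblage
#'
#' MRD is the arithmetic mean of root distance over the species of a reserve,
#' each species weighted equally via its order's RD. Species whose order is
#' absent from the RD table are excluded with a warning and reported in the
#' returned count, never imputed.
#'
#' @param asm An [assemblage()].
#' @param rd A named RD vector from [root_distances()].
#' @return A list with \code{mrd}, \code{n_used}, \code{n_excluded}, and
#'   \code{excluded_orders}.
#' @examples
#' rd <- root_distances(read_order_tree("((A,B),C);"))
#' asm <- assemblage("r1", c("s1", "s2"), c("A", "C"))
#' mean_root_distance(asm, rd)$mrd  # 1.5
#' @export
mean_root_distance <- function(asm, rd) {
  if (nrow(asm) == 0L) stop("assemblage is empty", call. = FALSE)
  known <- asm$order %in% names(rd)
  if (!any(known)) {
    stop("no scorable species: none of the orders appear in the RD table",
         call. = FALSE)
  }
  excl <- asm$order[!known]
  if (length(excl)) {
    warning(length(excl), " species in orders absent from the RD table ",
            "excluded from MRD (", paste(unique(excl), collapse = ", "), ")",
            call. = FALSE)
  }
  vals <- rd[asm$order[known]]
  list(mrd = mean(vals),
       n_used = sum(known),
       n_excluded = sum(!known),
       excluded_orders = unique(excl))
}

#' Richness counts of an assemblage by thermal origin or biogeographic affinity
#'
#' @param asm An [assemblage()].
#' @param by \code{"thermal"} (warm/cold clades via the clade-origin table) or
#'   \code{"affinity"} (Oriental/Palearctic/widespread labels on the records).
#' @param table Clade-origin table used when \code{by = "thermal"}.
#' @return A list with \code{counts} (named integer vector over the classifiable
#'   groups) and \code{unclassified} (count of records outside them).
#' @export
group_richness <- function(asm, by = c("thermal", "affinity"),
                           table = clade_origin_table()) {
  by <- match.arg(by)
  if (by == "affinity") {
    if (is.null(asm$affinity)) {
      stop("assemblage carries no affinity labels", call. = FALSE)
    }
    lev <- c("Oriental", "Palearctic", "widespread")
    lab <- asm$affinity
  } else {
    lev <- c("warm", "cold")
    lab <- if (nrow(asm)) classify_thermal_origin(asm$order, table) else character(0)
  }
  counts <- vapply(lev, function(g) sum(lab == g, na.rm = TRUE), integer(1L))
  list(counts = counts,
       unclassified = nrow(asm) - sum(counts))
}
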