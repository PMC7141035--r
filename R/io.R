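#' Read an ESRI ASCII grid
#'
#' Supports the standard six-line header (ncols, nrows, xllcorner/xllcenter,
#' yllcorner/yllcenter, cellsize, nodata_value) followed by whitespace-
#' separated rows, north row first.
#'
#' @param path File path.
#' @return A [grid_layer()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    stop("ASCII grid header missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2 else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2 else 0
  grid_layer(m, cellsize = hdr$cellsize, xll = xll, yll = yll, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param layer A [grid_layer()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ascii_grid <- function(layer, path) {
  stopifnot(inherits(layer, "grid_layer"))
  v <- layer$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(layer$xll, scientific = FALSE)),
    paste("yllcorner", format(layer$yll, scientific = FALSE)),
    paste("cellsize", format(layer$cellsize, scientific = FALSE)),
    paste("nodata_value", format(layer$nodata, scientific = FALSE))), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = " ")
  invisible(path)
}

reserve_required_cols <- function() {
  c("reserve_id", "lat", "lon", "MAP", "PET", "PET2", "MTCM", "NDVI",
    "AREA", "E_max", "NCT", "TR", "GDP", "POP",
    "LGM_MAP", "LGM_MTCM", "T_Anomaly")
}

#' Read a per-reserve covariate table
#'
#' Comma-delimited UTF-8 text with a header carrying the covariate field
#' names exactly. Missing required columns and non-numeric cells are
#' reported by name and position. Extra columns are kept untouched.
#'
#' @param path File path.
#' @return A validated data.frame, one row per reserve.
#' @export
read_reserves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(reserve_required_cols(), names(df))
  if (length(miss)) {
    stop("reserve table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(reserve_required_cols(), "reserve_id")
  for (cc in num_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad)) {
        stop("non-numeric value in column '", cc, "', row ", bad[1L],
             ": '", v[bad[1L]], "'", call. = FALSE)
      }
      df[[cc]] <- vn
    }
  }
  if (anyDuplicated(df$reserve_id)) {
    stop("duplicate reserve_id in reserve table", call. = FALSE)
  }
  message(nrow(df), " reserves read from ", path)
  df
}

#' Write a per-reserve covariate table
#'
#' @param reserves Data.frame from [simulate_reserves()] or [read_reserves()].
#' @param path Output path.
#' @export
write_reserves <- function(reserves, path) {
  utils::write.csv(reserves, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read species lists into assemblages
#'
#' Expects comma-delimited text with header \code{reserve_id}, \code{species},
#' \code{order} and optionally \code{affinity}. Duplicate (reserve, species)
#' rows are an error; a species assigned to different orders in different
#' rows is also an error, never silently de-duplicated.
#'
#' @param path File path.
#' @return Named list of [assemblage()] objects, one per reserve.
#' @export
read_species_lists <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("reserve_id", "species", "order")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("species list missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$reserve_id, df$species, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate species row: reserve '", d$reserve_id, "', species '",
         d$species, "'", call. = FALSE)
  }
  ord_per_sp <- tapply(df$order, df$species, function(o) length(unique(o)))
  multi <- names(ord_per_sp)[ord_per_sp > 1L]
  if (length(multi)) {
    stop("species assigned to multiple orders: ",
         paste(utils::head(multi, 5L), collapse = ", "), call. = FALSE)
  }
  has_aff <- "affinity" %in% names(df)
  if (!has_aff) {
    warning("no 'affinity' column: affinity analyses disabled", call. = FALSE)
  }
  out <- lapply(split(df, df$reserve_id), function(d) {
    assemblage(d$reserve_id[1L], d$species, d$order,
               affinity = if (has_aff) d$affinity else NULL)
  })
  message(length(out), " assemblages read from ", path)
  out
}

#' Write assemblages as a species-list table
#'
#' @param assemblages List of [assemblage()] objects.
#' @param path Output path.
#' @export
write_species_lists <- function(assemblages, path) {
  df <- do.call(rbind, lapply(assemblages, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Occurrence matrix to species-list assemblages
#'
#' @param dataset A [simulate_dataset()] result.
#' @return Named list of [assemblage()] objects (empty reserves omitted).
#' @export
dataset_to_assemblages <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  occ <- dataset$occurrences
  pool <- dataset$pool
  out <- list()
  for (r in rownames(occ)) {
    i <- occ[r, ]
    if (!any(i)) next
    out[[r]] <- assemblage(r, pool$species[i], pool$order[i],
                           affinity = pool$affinity[i])
  }
  out
}

#' Run configuration for the end-to-end pipeline
#'
#' Every stage reads its settings from this object only; unknown keys are
#' rejected to catch typos early.
#'
#' @param ... Named settings overriding the defaults: \code{tree},
#'   \code{species_lists}, \code{reserves} (paths or in-memory objects),
#'   \code{out_dir}, \code{seed}, \code{n_trees}, \code{moran_classes},
#'   \code{moran_perms}, \code{rd_convention}, \code{log_richness},
#'   \code{verbose}.
#' @return A \code{"run_config"} list.
#' @export
run_config <- function(...) {
  defaults <- list(tree = NULL, species_lists = NULL, reserves = NULL,
                   out_dir = tempfile("phylograd_run_"), seed = 1L,
                   n_trees = 200L, moran_classes = 10L, moran_perms = 999L,
                   rd_convention = "root-inclusive", log_richness = TRUE,
                   verbose = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "run_config")
}

#' Run the full pipeline: MRD, gradients, importance
#'
#' Reads (or accepts in memory) the order tree, the species lists and the
#' reserve covariates; computes per-reserve MRD overall and per thermal
#' clade; fits latitudinal gradients with quadratic peaks; builds the
#' bivariate variance-explained table; and runs the multivariate importance
#' stage (AIC/VIF pruning, seeded random forest, Moran's I residual
#' correlogram) for total richness and overall MRD. All artifacts are written
#' under \code{config$out_dir}; identical inputs and seed give identical
#' output files.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results and the paths written.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  tree <- if (inherits(config$tree, "phylo")) config$tree
          else read_order_tree(config$tree)
  asms <- if (is.list(config$species_lists) &&
              all(vapply(config$species_lists, inherits, logical(1L),
                         "assemblage"))) {
    config$species_lists
  } else {
    read_species_lists(config$species_lists)
  }
  reserves <- if (is.data.frame(config$reserves)) config$reserves
              else read_reserves(config$reserves)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  rd <- root_distances(tree, convention = config$rd_convention)
  origin <- clade_origin_table()
  per_res <- lapply(asms, function(a) {
    m_all <- suppressWarnings(mean_root_distance(a, rd))
    clade <- classify_thermal_origin(a$order, origin)
    sub_mrd <- function(cl) {
      i <- clade == cl & a$order %in% names(rd)
      if (!any(i)) NA_real_ else mean(rd[a$order[i]])
    }
    gr <- group_richness(a, "thermal", origin)
    data.frame(reserve_id = a$reserve_id[1L], richness = nrow(a),
               warm_richness = gr$counts[["warm"]],
               cold_richness = gr$counts[["cold"]],
               mrd = m_all$mrd, mrd_warm = sub_mrd("warm"),
               mrd_cold = sub_mrd("cold"),
               n_excluded = m_all$n_excluded, stringsAsFactors = FALSE)
  })
  mrd_tab <- do.call(rbind, per_res)
  rownames(mrd_tab) <- NULL
  merged <- merge(reserves, mrd_tab, by = "reserve_id")
  say(nrow(merged), " reserves with both covariates and species lists")

  fits <- list(
    richness_quad = fit_latitudinal(merged$richness, merged$lat, "quadratic",
                                    log_y = config$log_richness,
                                    response = "richness"),
    warm_richness_quad = fit_latitudinal(merged$warm_richness, merged$lat,
                                         "quadratic",
                                         log_y = config$log_richness,
                                         response = "warm_richness"),
    cold_richness_quad = fit_latitudinal(merged$cold_richness, merged$lat,
                                         "quadratic",
                                         log_y = config$log_richness,
                                         response = "cold_richness"),
    mrd_linear = fit_latitudinal(merged$mrd, merged$lat, "linear",
                                 response = "mrd"),
    mrd_warm_linear = fit_latitudinal(merged$mrd_warm, merged$lat, "linear",
                                      response = "mrd_warm"),
    mrd_cold_linear = fit_latitudinal(merged$mrd_cold, merged$lat, "linear",
                                      response = "mrd_cold"))
  peaks <- lapply(fits[c("richness_quad", "warm_richness_quad",
                         "cold_richness_quad")], peak_latitude)

  predictors <- c("NDVI", "MAP", "PET", "PET2", "AREA", "E_max", "NCT", "TR",
                  "GDP", "POP", "MTCM", "LGM_MAP", "LGM_MTCM", "T_Anomaly")
  responses <- merged[, c("richness", "warm_richness", "cold_richness",
                          "mrd", "mrd_warm", "mrd_cold")]
  biv <- bivariate_table(merged, responses, predictors = predictors,
                         log_responses = c("richness", "warm_richness",
                                           "cold_richness"))

  reports <- list()
  for (resp in c("richness", "mrd")) {
    spec <- model_spec(response = resp, predictors = predictors,
                       log_response = resp == "richness" && config$log_richness,
                       n_trees = config$n_trees,
                       n_classes = config$moran_classes,
                       n_perm = config$moran_perms, seed = config$seed)
    reports[[resp]] <- run_importance_stage(merged, spec)
  }

  paths <- list(
    bivariate = file.path(config$out_dir, "bivariate_table.csv"),
    importance = file.path(config$out_dir, "importance_matrix.csv"),
    report = file.path(config$out_dir, "report.json"),
    log = file.path(config$out_dir, "run.log"))
  utils::write.csv(biv, paths$bivariate, row.names = FALSE, quote = FALSE)
  write_importance_matrix(reports, paths$importance)
  fit_json <- list(
    seed = config$seed,
    fits = lapply(fits, function(f) f[c("response", "shape", "coefficients",
                                        "r_squared", "p_value", "n")]),
    peaks = peaks,
    importance = lapply(reports, function(r) list(
      retained = r$retained, dropped = r$dropped,
      importance = as.list(r$importance),
      residuals_independent = r$residuals_independent)))
  jsonlite::write_json(fit_json, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(c(paste("seed:", config$seed),
               paste("phylograd:",
                     as.character(utils::packageVersion("phylograd"))),
               paste("R:", R.version.string),
               paste("reserves:", nrow(merged))), paths$log)
  say("artifacts written to ", config$out_dir)
  invisible(list(mrd = mrd_tab, merged = merged, fits = fits, peaks = peaks,
                 bivariate = biv, importance = reports, paths = paths))
}

#' Write the importance reports as a predictor x response matrix
#'
#' Blank cells mark predictors dropped before the forest; values are given
#' to two decimals; an attribute row distinguishes AIC drops from VIF drops
#' in the accompanying long-format columns.
#'
#' @param reports Named list of importance reports.
#' @param path Output path.
#' @export
write_importance_matrix <- function(reports, path) {
  all_pred <- unique(unlist(lapply(reports, function(r)
    c(r$retained, r$dropped$predictor))))
  m <- matrix("", nrow = length(all_pred), ncol = length(reports),
              dimnames = list(all_pred, names(reports)))
  for (nm in names(reports)) {
    r <- reports[[nm]]
    m[names(r$importance), nm] <- sprintf("%.2f", r$importance)
    if (nrow(r$dropped)) {
      m[r$dropped$predictor, nm] <- paste0("dropped:", r$dropped$reason)
    }
  }
  df <- data.frame(predictor = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
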