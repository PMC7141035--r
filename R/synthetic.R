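#' Default order-level phylogeny for the simulator
#'
#' A small rooted newick phylogeny over ten insect orders whose node-count
#' depths encode the usual basal-to-derived ladder: apterygote orders branch
#' first and the holometabolan orders sit deepest. Its root distances are the
#' simulator's default per-order RD values, so simulated data and the tree
#' readers exercise the same code paths.
#'
#' @return A \code{"phylo"} object.
#' @export
default_order_tree <- function() {
  read_order_tree(paste0(
    "(Archaeognatha,(Zygentoma,(Odonata,(Orthoptera,(Hemiptera,",
    "(Hymenoptera,(Coleoptera,(Mecoptera,(Lepidoptera,Diptera)))))))));"
  ))
}

#' Configuration for the niche-conservatism assemblage simulator
#'
#' The generator encodes the mechanisms the analysis is designed to detect:
#' a linear winter-coldness gradient with latitude, stronger glacial cooling
#' in the north, species pools whose thermal tolerance limits differ by
#' biogeographic affinity (Oriental species intolerant of cold, Palearctic
#' species excluded from the warm south, widespread species occupying a
#' midlatitude band), and a coupling that makes evolutionarily derived
#' (high-RD) orders more cold-tolerant — steeper within the warm-originated
#' clades than the cold-originated ones. Occupancy is a deterministic
#' interval filter on glacial-maximum winter coldness.
#'
#' @param n_reserves Number of reserves.
#' @param lat_range,lon_range Latitude / longitude spans (decimal degrees).
#' @param seed Mandatory integer seed.
#' @param pool_sizes Named species counts for Oriental, Palearctic, widespread.
#' @param cold_limit,warm_limit Per-affinity Gaussian (mean, sd) for the
#'   lower / upper tolerated LGM winter temperature (degrees C).
#' @param mtcm_c0,mtcm_c1 Current winter coldness gradient:
#'   MTCM = c0 - c1 * lat + noise.
#' @param lgm_cooling LGM cooling offset: \code{base} +
#'   \code{per_deg} * (lat - southern edge), subtracted from MTCM.
#' @param rd_table Named per-order root distances (default: the modeled six
#'   orders of [default_order_tree()]).
#' @param cold_shift Degrees C of extra cold tolerance per RD node above
#'   \code{rd_ref}, one value per thermal-origin clade (warm steeper).
#' @param rd_ref Reference RD at which the shift is zero.
#' @param noise Global multiplier on every covariate noise sd (0 = exact
#'   gradients).
#' @param occupancy \code{"filter"} (the niche-conservatism interval rule) or
#'   \code{"random"} (seeded Bernoulli null with no geographic signal).
#' @param occupancy_p Presence probability under \code{occupancy = "random"}.
#' @param filter_var Climate variable keying the filter; the default is LGM
#'   winter coldness, the historical-signal hypothesis.
#' @return A \code{"sim_config"} list.
#' @export
sim_config <- function(n_reserves = 110,
                       lat_range = c(19.1, 51.5),
                       lon_range = c(82, 130),
                       seed,
                       pool_sizes = c(Oriental = 150, Palearctic = 150,
                                      widespread = 200),
                       cold_limit = list(
                         Oriental   = c(mean = -2,  sd = 4),
                         Palearctic = c(mean = -35, sd = 5),
                         widespread = c(mean = -20, sd = 4)),
                       warm_limit = list(
                         Oriental   = c(mean = 40, sd = 3),
                         Palearctic = c(mean = -8, sd = 5),
                         widespread = c(mean = 8,  sd = 5)),
                       mtcm_c0 = 42, mtcm_c1 = 1.4,
                       lgm_cooling = c(base = 4, per_deg = 0.15),
                       rd_table = NULL,
                       cold_shift = c(warm = 4, cold = 3),
                       rd_ref = 6,
                       noise = 1,
                       occupancy = c("filter", "random"),
                       occupancy_p = 0.5,
                       filter_var = c("LGM_MTCM", "MTCM")) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  occupancy <- match.arg(occupancy)
  filter_var <- match.arg(filter_var)
  if (any(lat_range < -90) || any(lat_range > 90) || diff(lat_range) <= 0) {
    stop("invalid latitude range", call. = FALSE)
  }
  if (any(pool_sizes < 1)) stop("pool sizes must be >= 1", call. = FALSE)
  if (noise < 0) stop("'noise' must be >= 0", call. = FALSE)
  affs <- c("Oriental", "Palearctic", "widespread")
  if (!all(affs %in% names(pool_sizes)) ||
      !all(affs %in% names(cold_limit)) || !all(affs %in% names(warm_limit))) {
    stop("pool_sizes, cold_limit, warm_limit must name all three affinities",
         call. = FALSE)
  }
  sds <- c(vapply(cold_limit, `[[`, numeric(1L), "sd"),
           vapply(warm_limit, `[[`, numeric(1L), "sd"))
  if (any(sds < 0)) stop("tolerance sds must be >= 0", call. = FALSE)
  if (is.null(rd_table)) {
    rd_all <- root_distances(default_order_tree())
    rd_table <- rd_all[clade_origin_table()$order]
  }
  structure(list(n_reserves = n_reserves, lat_range = lat_range,
                 lon_range = lon_range, seed = as.integer(seed),
                 pool_sizes = pool_sizes, cold_limit = cold_limit,
                 warm_limit = warm_limit, mtcm_c0 = mtcm_c0,
                 mtcm_c1 = mtcm_c1, lgm_cooling = lgm_cooling,
                 rd_table = rd_table, cold_shift = cold_shift,
                 rd_ref = rd_ref, noise = noise, occupancy = occupancy,
                 occupancy_p = occupancy_p, filter_var = filter_var),
            class = "sim_config")
}

#' Simulate reserves and their environmental covariates
#'
#' Latitudes are uniform over the configured span; longitudes uniform (no
#' east-west structure is generated). Winter coldness follows the configured
#' linear gradient; glacial-maximum analogues subtract a cooling offset that
#' grows northward; the remaining covariates follow simple declared equations
#' with seeded Gaussian noise (the \code{equations} attribute records every
#' form used).
#'
#' @param config A [sim_config()].
#' @return Data.frame of reserves with \code{reserve_id}, \code{lat},
#'   \code{lon} and the full covariate set.
#' @export
simulate_reserves <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reserves
  ns <- config$noise
  lat <- stats::runif(n, config$lat_range[1L], config$lat_range[2L])
  lon <- stats::runif(n, config$lon_range[1L], config$lon_range[2L])
  lat0 <- config$lat_range[1L]
  mtcm <- config$mtcm_c0 - config$mtcm_c1 * lat + stats::rnorm(n, 0, 3 * ns)
  cooling <- config$lgm_cooling[["base"]] +
    config$lgm_cooling[["per_deg"]] * (lat - lat0) + stats::rnorm(n, 0, 2 * ns)
  lgm_mtcm <- mtcm - cooling
  mat <- 38 - 0.85 * lat + stats::rnorm(n, 0, 1.5 * ns)
  lgm_mat <- mat - (5 + 0.1 * (lat - lat0)) + stats::rnorm(n, 0, 1 * ns)
  map <- pmax(50, 2200 - 55 * (lat - lat0) + stats::rnorm(n, 0, 150 * ns))
  lgm_map <- pmax(30, 0.75 * map + stats::rnorm(n, 0, 100 * ns))
  pet <- 1500 - 25 * (lat - lat0) + stats::rnorm(n, 0, 60 * ns)
  ndvi <- pmin(0.95, pmax(0.05,
                0.85 - 0.009 * (lat - lat0) + stats::rnorm(n, 0, 0.05 * ns)))
  e_max <- exp(stats::rnorm(n, 7.3, 0.6))
  nct <- 1L + stats::rpois(n, 24)
  tr <- 1 + stats::rexp(n, rate = 8)
  gdp <- exp(stats::rnorm(n, 6, 1))
  pop <- exp(stats::rnorm(n, 4.5, 1))
  area <- exp(stats::rnorm(n, 9.2, 1))
  out <- data.frame(
    reserve_id = sprintf("R%03d", seq_len(n)),
    lat = lat, lon = lon,
    MAP = map, PET = pet, PET2 = pet^2, MTCM = mtcm, NDVI = ndvi,
    AREA = area, E_max = e_max, NCT = nct, TR = tr, GDP = gdp, POP = pop,
    LGM_MAP = lgm_map, LGM_MTCM = lgm_mtcm, T_Anomaly = mat - lgm_mat,
    stringsAsFactors = FALSE)
  attr(out, "equations") <- c(
    MTCM = sprintf("%g - %g*lat + N(0, %g)", config$mtcm_c0, config$mtcm_c1, 3 * ns),
    LGM_MTCM = sprintf("MTCM - (%g + %g*(lat-%g)) - N(0, %g)",
                       config$lgm_cooling[["base"]],
                       config$lgm_cooling[["per_deg"]], lat0, 2 * ns),
    MAP = sprintf("max(50, 2200 - 55*(lat-%g) + N(0, %g))", lat0, 150 * ns),
    LGM_MAP = sprintf("max(30, 0.75*MAP + N(0, %g))", 100 * ns),
    PET = sprintf("1500 - 25*(lat-%g) + N(0, %g)", lat0, 60 * ns),
    NDVI = sprintf("clamp(0.85 - 0.009*(lat-%g) + N(0, %g), 0.05, 0.95)",
                   lat0, 0.05 * ns),
    T_Anomaly = "MAT - LGM_MAT, MAT = 38 - 0.85*lat",
    E_max = "lognormal(7.3, 0.6)", NCT = "1 + Pois(24)",
    TR = "1 + Exp(8)", GDP = "lognormal(6, 1)", POP = "lognormal(4.5, 1)",
    AREA = "lognormal(9.2, 1)")
  out
}

#' Simulate a species pool with affinity- and clade-structured tolerances
#'
#' Each species gets an affinity, an order drawn uniformly from the modelled
#' set, and Gaussian cold / warm tolerance limits. The cold limit is shifted
#' downward by \code{cold_shift[clade] * (RD - rd_ref)} degrees, so derived
#' (high-RD) orders are stochastically more cold-tolerant, with a steeper
#' coupling inside the warm-originated clades.
#'
#' @param config A [sim_config()].
#' @return Data.frame: \code{species}, \code{affinity}, \code{order},
#'   \code{rd}, \code{cold_limit}, \code{warm_limit}.
#' @export
simulate_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  affs <- rep(names(config$pool_sizes), times = config$pool_sizes)
  n <- length(affs)
  # balanced order composition within each affinity: every affinity spreads
  # its species evenly over the modelled orders, so between-affinity MRD
  # baselines differ only through the tolerance draws, not sampling noise
  orders <- unlist(lapply(config$pool_sizes, function(k)
    rep_len(names(config$rd_table), k)), use.names = FALSE)
  rd <- config$rd_table[orders]
  clade <- classify_thermal_origin(orders)
  shift <- ifelse(clade %in% names(config$cold_shift),
                  config$cold_shift[clade], 0) * (rd - config$rd_ref)
  cmu <- vapply(config$cold_limit, `[[`, numeric(1L), "mean")[affs]
  csd <- vapply(config$cold_limit, `[[`, numeric(1L), "sd")[affs]
  wmu <- vapply(config$warm_limit, `[[`, numeric(1L), "mean")[affs]
  wsd <- vapply(config$warm_limit, `[[`, numeric(1L), "sd")[affs]
  cold <- stats::rnorm(n, cmu - shift, csd)
  warm <- stats::rnorm(n, wmu, wsd)
  # guarantee a nonempty tolerance interval
  warm <- pmax(warm, cold)
  data.frame(species = sprintf("sp%04d", seq_len(n)),
             affinity = affs, order = orders, rd = unname(rd),
             cold_limit = cold, warm_limit = warm,
             stringsAsFactors = FALSE)
}

#' Assemble occurrences from a pool and a reserve network
#'
#' Under the default filter rule, species i occurs at reserve r iff the
#' reserve's (glacial-maximum) winter coldness lies inside the species'
#' tolerated interval: \code{cold_limit <= climate <= warm_limit}.
#' Deterministic given its inputs. The \code{"random"} occupancy mode draws
#' seeded Bernoulli presences with no geographic structure.
#'
#' @param pool From [simulate_pool()].
#' @param reserves From [simulate_reserves()].
#' @param config The shared [sim_config()].
#' @return Logical matrix, reserves x species.
#' @export
assemble <- function(pool, reserves, config) {
  stopifnot(inherits(config, "sim_config"))
  n_r <- nrow(reserves); n_s <- nrow(pool)
  if (config$occupancy == "random") {
    set.seed(config$seed + 2L)
    occ <- matrix(stats::runif(n_r * n_s) < config$occupancy_p, n_r, n_s)
  } else {
    clim <- reserves[[config$filter_var]]
    occ <- outer(clim, pool$cold_limit, `>=`) &
           outer(clim, pool$warm_limit, `<=`)
  }
  dimnames(occ) <- list(reserves$reserve_id, pool$species)
  occ
}

#' Simulate a complete dataset with recorded generative truth
#'
#' @param config A [sim_config()].
#' @return A \code{"synthetic_dataset"} list: \code{reserves}, \code{pool},
#'   \code{occurrences}, and \code{truth} (the generative driver, the filter
#'   rule, the niche parameters, the RD table, and the latitude band where
#'   the widespread-affinity overlap peak is expected).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  reserves <- simulate_reserves(config)
  pool <- simulate_pool(config)
  occ <- assemble(pool, reserves, config)
  # invert the mean LGM winter gradient at the widespread limits to get the
  # latitude band where the midlatitude overlap peak should fall
  lat0 <- config$lat_range[1L]
  slope <- config$mtcm_c1 + config$lgm_cooling[["per_deg"]]
  icept <- config$mtcm_c0 - config$lgm_cooling[["base"]] +
    config$lgm_cooling[["per_deg"]] * lat0
  lat_at <- function(L) (icept - L) / slope
  band <- sort(c(lat_at(config$warm_limit$widespread[["mean"]]),
                 lat_at(config$cold_limit$widespread[["mean"]])))
  structure(list(
    reserves = reserves, pool = pool, occurrences = occ,
    truth = list(driver = if (config$occupancy == "filter")
                   config$filter_var else "none",
                 rule = if (config$occupancy == "filter")
                   "present iff cold_limit <= climate <= warm_limit"
                 else sprintf("Bernoulli(%g), no geographic signal",
                              config$occupancy_p),
                 niche = list(cold_limit = config$cold_limit,
                              warm_limit = config$warm_limit,
                              cold_shift = config$cold_shift,
                              rd_ref = config$rd_ref),
                 rd_table = config$rd_table,
                 expected_peak_band = band,
                 equations = attr(reserves, "equations"),
                 config = config)),
    class = "synthetic_dataset")
}

#' Per-reserve richness and MRD summaries of a synthetic dataset
#'
#' @param dataset A [simulate_dataset()] result.
#' @return Data.frame keyed by reserve: total and per-affinity richness,
#'   warm/cold clade richness, and MRD overall and per clade.
#' @export
dataset_summaries <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  occ <- dataset$occurrences
  pool <- dataset$pool
  rd <- dataset$truth$rd_table
  clade <- classify_thermal_origin(pool$order)
  mrd_of <- function(present, sel) {
    i <- present & sel
    if (!any(i)) NA_real_ else mean(rd[pool$order[i]])
  }
  res <- dataset$reserves
  out <- data.frame(
    reserve_id = res$reserve_id, lat = res$lat, lon = res$lon,
    richness = rowSums(occ),
    oriental = rowSums(occ[, pool$affinity == "Oriental", drop = FALSE]),
    palearctic = rowSums(occ[, pool$affinity == "Palearctic", drop = FALSE]),
    widespread = rowSums(occ[, pool$affinity == "widespread", drop = FALSE]),
    warm_richness = rowSums(occ[, clade == "warm", drop = FALSE]),
    cold_richness = rowSums(occ[, clade == "cold", drop = FALSE]),
    stringsAsFactors = FALSE)
  out$mrd <- apply(occ, 1L, mrd_of, sel = rep(TRUE, nrow(pool)))
  out$mrd_warm <- apply(occ, 1L, mrd_of, sel = clade == "warm")
  out$mrd_cold <- apply(occ, 1L, mrd_of, sel = clade == "cold")
  out
}

#' Check the geographic patterns a default simulation should show
#'
#' Recomputes, from the occurrence matrix, the four diagnostic patterns the
#' generator is built to produce: Oriental richness falling and Palearctic
#' richness rising with latitude (Spearman), a concave quadratic for total
#' richness with an interior peak, and a positive MRD-latitude slope; plus
#' the warm-versus-cold MRD slope contrast. Each is reported with its test
#' statistic, p-value and a pass flag at alpha = .05.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param alpha Significance level for the pass flags.
#' @return Data.frame: \code{property}, \code{value}, \code{p_value},
#'   \code{pass}.
#' @export
expected_patterns <- function(dataset, alpha = 0.05) {
  sm <- dataset_summaries(dataset)
  safe_spearman <- function(x, y) {
    if (stats::var(y) == 0) return(list(estimate = 0, p.value = 1))
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    list(estimate = unname(ct$estimate), p.value = ct$p.value)
  }
  ori <- safe_spearman(sm$lat, sm$oriental)
  pal <- safe_spearman(sm$lat, sm$palearctic)
  quad <- fit_latitudinal(sm$richness, sm$lat, "quadratic", log_y = TRUE,
                          response = "total richness")
  pk <- peak_latitude(quad)
  mrd_all <- fit_latitudinal(sm$mrd, sm$lat, "linear", response = "MRD")
  mrd_w <- fit_latitudinal(sm$mrd_warm, sm$lat, "linear", response = "MRD warm")
  mrd_c <- fit_latitudinal(sm$mrd_cold, sm$lat, "linear", response = "MRD cold")
  rows <- rbind(
    data.frame(property = "oriental_richness_decreases",
               value = ori$estimate, p_value = ori$p.value,
               pass = ori$estimate < 0 & ori$p.value < alpha),
    data.frame(property = "palearctic_richness_increases",
               value = pal$estimate, p_value = pal$p.value,
               pass = pal$estimate > 0 & pal$p.value < alpha),
    data.frame(property = "total_richness_humped_interior_peak",
               value = quad$coefficients[["a"]], p_value = quad$p_value,
               pass = quad$coefficients[["a"]] < 0 & quad$p_value < alpha &
                 !is.na(pk$peak)),
    data.frame(property = "mrd_increases_with_latitude",
               value = mrd_all$coefficients[["b"]], p_value = mrd_all$p_value,
               pass = mrd_all$coefficients[["b"]] > 0 &
                 mrd_all$p_value < alpha),
    data.frame(property = "warm_mrd_slope_exceeds_cold",
               value = mrd_w$coefficients[["b"]] - mrd_c$coefficients[["b"]],
               p_value = max(mrd_w$p_value, mrd_c$p_value),
               pass = mrd_w$coefficients[["b"]] > mrd_c$coefficients[["b"]] &
                 mrd_w$coefficients[["b"]] > 0 & mrd_w$p_value < alpha &
                 mrd_c$coefficients[["b"]] > 0 & mrd_c$p_value < alpha))
  rownames(rows) <- NULL
  rows
}
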