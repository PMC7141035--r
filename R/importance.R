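#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j comes from regressing predictor j on
#' all the others. Computed via the diagonal of the inverse correlation
#' matrix; exact collinearity is reported as \code{Inf} rather than an error.
#'
#' @param design Numeric matrix or data.frame of predictors (>= 2 columns,
#'   more rows than columns + 1).
#' @return Named numeric vector of VIFs.
#' @examples
#' x <- matrix(rnorm(200), 100, 2)
#' vif(x)  # both close to 1
#' @export
vif <- function(design) {
  x <- as.matrix(design)
  if (ncol(x) < 2L) stop("need at least 2 predictors for VIF", call. = FALSE)
  if (nrow(x) <= ncol(x) + 1L) {
    stop("need more rows than predictors + 1", call. = FALSE)
  }
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(x)[sds == 0]
    if (is.null(nm)) nm <- which(sds == 0)
    stop("constant column(s): ", paste(nm, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(x)
  out <- tryCatch(diag(solve(r)), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out)) || any(out < 0)) {
    # singular correlation matrix: fall back to per-column auxiliary R^2
    out <- vapply(seq_len(ncol(x)), function(j) {
      # a perfect auxiliary fit is exactly the case handled here, so the
      # perfect-fit warning from summary.lm carries no information
      r2 <- suppressWarnings(
        summary(stats::lm(x[, j] ~ x[, -j, drop = FALSE]))$r.squared)
      if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1L))
  }
  names(out) <- colnames(x)
  out
}

#' Model specification for the multivariate importance stage
#'
#' @param response Response column name.
#' @param predictors Candidate predictor column names (declaration order is
#'   the tie-break order everywhere downstream).
#' @param log_response Natural-log the response (richness-type) before
#'   modelling?
#' @param log_area Enter \code{AREA} as its natural log?
#' @param n_trees Number of regression trees in the random forest.
#' @param vif_threshold Predictors with VIF above this are pruned.
#' @param prune_order \code{"aic_then_vif"} (default) or \code{"vif_then_aic"}.
#' @param n_classes,n_perm Moran's I distance classes and permutations.
#' @param seed Mandatory seed governing bootstrap and permutation draws.
#' @return A \code{"model_spec"} list.
#' @export
model_spec <- function(response, predictors, log_response = FALSE,
                       log_area = TRUE, n_trees = 200, vif_threshold = 10,
                       prune_order = c("aic_then_vif", "vif_then_aic"),
                       n_classes = 10, n_perm = 999, seed) {
  if (missing(seed)) stop("'seed' is mandatory in a model_spec", call. = FALSE)
  if (!length(predictors)) stop("candidate predictors must be nonempty", call. = FALSE)
  structure(list(response = response, predictors = predictors,
                 log_response = log_response, log_area = log_area,
                 n_trees = n_trees, vif_threshold = vif_threshold,
                 prune_order = match.arg(prune_order),
                 n_classes = n_classes, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "model_spec")
}

prepare_model_frame <- function(data, spec) {
  cols <- c(spec$response, spec$predictors)
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop("column(s) absent from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- data[, cols, drop = FALSE]
  idx <- seq_len(nrow(df))
  if (spec$log_area && "AREA" %in% spec$predictors) df$AREA <- log(df$AREA)
  if (spec$log_response) {
    keep <- df[[spec$response]] > 0
    df <- df[keep, , drop = FALSE]
    idx <- idx[keep]
    df[[spec$response]] <- log(df[[spec$response]])
  }
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  attr(df, "row_index") <- idx[cc]
  df
}

#' Prune candidate predictors by AIC then VIF
#'
#' Stage 1: backward elimination on an OLS of the (transformed) response,
#' removing single predictors while any removal lowers AIC. Stage 2:
#' iteratively remove the predictor with the largest VIF among the survivors
#' until all VIFs are at or below the threshold. Both stages are
#' deterministic; ties are broken by declaration order. The stage order can
#' be flipped via the spec.
#'
#' @param data Data.frame holding the response and candidates.
#' @param spec A [model_spec()].
#' @return A list with \code{retained} (character) and \code{dropped}
#'   (data.frame of \code{predictor}, \code{reason} in \{"AIC", "VIF"\}).
#' @export
prune_predictors <- function(data, spec) {
  df <- prepare_model_frame(data, spec)
  p <- length(spec$predictors)
  if (nrow(df) < 10L) stop("need at least 10 complete cases", call. = FALSE)
  if (nrow(df) < p + 2L) {
    stop("fewer complete cases than predictors + 2", call. = FALSE)
  }
  dropped <- data.frame(predictor = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  retained <- spec$predictors

  aic_stage <- function(retained, dropped) {
    if (length(retained) < 1L) return(list(retained, dropped))
    repeat {
      if (length(retained) == 1L) break
      form <- stats::reformulate(retained, response = spec$response)
      cur <- stats::AIC(stats::lm(form, data = df))
      cand_aic <- vapply(retained, function(v) {
        rest <- setdiff(retained, v)
        f <- stats::reformulate(rest, response = spec$response)
        stats::AIC(stats::lm(f, data = df))
      }, numeric(1L))
      if (min(cand_aic) >= cur) break
      drop_v <- retained[which.min(cand_aic)]  # which.min: first = declaration order
      retained <- setdiff(retained, drop_v)
      dropped <- rbind(dropped, data.frame(predictor = drop_v, reason = "AIC",
                                           stringsAsFactors = FALSE))
    }
    list(retained, dropped)
  }

  vif_stage <- function(retained, dropped) {
    repeat {
      if (length(retained) < 2L) break
      v <- vif(df[, retained, drop = FALSE])
      if (max(v) <= spec$vif_threshold) break
      drop_v <- retained[which.max(v)]
      retained <- setdiff(retained, drop_v)
      dropped <- rbind(dropped, data.frame(predictor = drop_v, reason = "VIF",
                                           stringsAsFactors = FALSE))
    }
    list(retained, dropped)
  }

  stages <- if (spec$prune_order == "aic_then_vif") {
    list(aic_stage, vif_stage)
  } else {
    list(vif_stage, aic_stage)
  }
  for (st in stages) {
    res <- st(retained, dropped)
    retained <- res[[1L]]
    dropped <- res[[2L]]
  }
  list(retained = retained, dropped = dropped)
}

#' Random-forest variable importance, normalised to the maximum
#'
#' Grows a regression forest of \code{spec$n_trees} bootstrap trees and takes
#' the out-of-bag permutation importance (mean decrease in accuracy, unscaled)
#' of each retained predictor. Negative raw importances are floored at zero,
#' then everything is divided by the maximum so the strongest predictor
#' scores exactly 1. Seeded, hence bitwise reproducible for fixed input order.
#'
#' @param data Data.frame holding response and predictors.
#' @param retained Character vector of predictors to enter the forest.
#' @param spec A [model_spec()].
#' @return A list with \code{importance} (named, max = 1), \code{raw}
#'   (unfloored permutation importances), \code{residuals} (out-of-bag
#'   response residuals), \code{oob_mse}, and the row index used.
#' @export
rf_importance <- function(data, retained, spec) {
  if (!length(retained)) stop("'retained' must be nonempty", call. = FALSE)
  sub_spec <- spec
  sub_spec$predictors <- retained
  df <- prepare_model_frame(data, sub_spec)
  if (nrow(df) < 10L) stop("need at least 10 complete cases", call. = FALSE)
  y <- df[[spec$response]]
  if (stats::var(y) == 0) stop("zero-variance response", call. = FALSE)
  x <- df[, retained, drop = FALSE]
  leak <- vapply(retained, function(v) {
    isTRUE(abs(stats::cor(x[[v]], y)) > 0.999999)
  }, logical(1L))
  if (any(leak)) {
    warning("predictor(s) numerically identical to the response: ",
            paste(retained[leak], collapse = ", "), call. = FALSE)
  }
  set.seed(spec$seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = spec$n_trees,
                                   importance = TRUE, keep.forest = TRUE)
  raw <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1L]
  floored <- pmax(raw, 0)
  if (max(floored) == 0) {
    # uninformative limit: nothing beats the permutation null, so the
    # normalised scale degenerates to an all-way tie
    warning("no informative predictors: all permutation importances <= 0; ",
            "importances tied at 1", call. = FALSE)
    imp <- rep(1, length(floored))
    names(imp) <- names(floored)
  } else {
    imp <- floored / max(floored)
  }
  list(importance = imp, raw = raw,
       residuals = y - rf$predicted, oob_mse = mean((y - rf$predicted)^2),
       rows = attr(df, "row_index"))
}

#' Moran's I correlogram with permutation tests
#'
#' Great-circle (haversine) distances between reserve centroids are split
#' into distance classes of approximately equal pair counts. Within class k,
#' with binary weights \eqn{w_{ij} = 1} iff pair (i, j) falls in the class,
#' \deqn{I_k = (n / \Sigma W) (\Sigma w_{ij} z_i z_j) / (\Sigma z_i^2)}
#' where z are mean-centred values. Two-sided p-values come from seeded
#' random permutations of the values over locations. The expectation under
#' randomisation is -1/(n-1).
#'
#' @param values Numeric vector (non-constant, n >= 10).
#' @param lon,lat Coordinates in decimal degrees (WGS84 assumed).
#' @param n_classes Number of equal-count distance classes.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation draws.
#' @return A data.frame with one row per class: \code{class}, \code{d_min},
#'   \code{d_max} (metres), \code{n_pairs}, \code{I}, \code{expected},
#'   \code{p_value}.
#' @export
morans_i <- function(values, lon, lat, n_classes = 10, n_perm = 999, seed = 1) {
  n <- length(values)
  if (n < 10L) stop("need n >= 10 locations", call. = FALSE)
  if (length(lon) != n || length(lat) != n) {
    stop("coordinate lengths differ from values", call. = FALSE)
  }
  if (stats::var(values) == 0) stop("values are constant", call. = FALSE)
  dmat <- geosphere::distm(cbind(lon, lat))
  pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  d <- dmat[cbind(pair_i, pair_j)]
  # equal-count classes via quantile breaks of the pairwise distances
  breaks <- unique(stats::quantile(d, probs = seq(0, 1, length.out = n_classes + 1L)))
  cls <- cut(d, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  z <- values - mean(values)
  s_z2 <- sum(z^2)
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
  out <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    idx <- if (k <= max(cls, na.rm = TRUE)) which(cls == k) else integer(0)
    if (!length(idx)) {
      out[[k]] <- data.frame(class = k, d_min = NA_real_, d_max = NA_real_,
                             n_pairs = 0L, I = NA_real_,
                             expected = -1 / (n - 1), p_value = NA_real_)
      next
    }
    ik <- pair_i[idx]; jk <- pair_j[idx]
    s0 <- 2 * length(idx)  # symmetric binary weights
    i_of <- function(zz) (n / s0) * (2 * sum(zz[ik] * zz[jk])) / sum(zz^2)
    i_obs <- (n / s0) * (2 * sum(z[ik] * z[jk])) / s_z2
    i_perm <- vapply(perms, function(p) i_of(z[p]), numeric(1L))
    p_ge <- (1 + sum(i_perm >= i_obs)) / (n_perm + 1)
    p_le <- (1 + sum(i_perm <= i_obs)) / (n_perm + 1)
    out[[k]] <- data.frame(class = k, d_min = min(d[idx]), d_max = max(d[idx]),
                           n_pairs = length(idx), I = i_obs,
                           expected = -1 / (n - 1),
                           p_value = min(1, 2 * min(p_ge, p_le)))
  }
  do.call(rbind, out)
}

#' Run the full multivariate importance stage
#'
#' Composes [prune_predictors()] (AIC then VIF), [rf_importance()] on the
#' survivors, and [morans_i()] on the forest's out-of-bag residuals. The
#' residuals are declared spatially independent when no distance class is
#' significant at a Bonferroni-corrected alpha across classes (a
#' correlogram-wide test); per-class raw p-values are reported untouched.
#'
#' @param data Data.frame with the response, candidate predictors, and
#'   \code{lon} / \code{lat} columns.
#' @param spec A [model_spec()].
#' @param alpha Correlogram-wide significance level (default 0.05).
#' @return An \code{"importance_report"} list: \code{retained},
#'   \code{dropped}, \code{importance}, \code{moran} (per-class table),
#'   \code{residuals_independent}, \code{seed}, \code{spec}.
#' @export
run_importance_stage <- function(data, spec, alpha = 0.05) {
  stopifnot(inherits(spec, "model_spec"))
  if (!all(c("lon", "lat") %in% names(data))) {
    stop("data must carry 'lon' and 'lat' columns", call. = FALSE)
  }
  pr <- prune_predictors(data, spec)
  if (!length(pr$retained)) stop("all predictors pruned", call. = FALSE)
  rf <- rf_importance(data, pr$retained, spec)
  rows <- rf$rows
  mi <- morans_i(rf$residuals, lon = data$lon[rows], lat = data$lat[rows],
                 n_classes = spec$n_classes, n_perm = spec$n_perm,
                 seed = spec$seed)
  k_tested <- sum(is.finite(mi$p_value))
  indep <- !any(mi$p_value < alpha / max(1L, k_tested), na.rm = TRUE)
  structure(list(response = spec$response,
                 retained = pr$retained, dropped = pr$dropped,
                 importance = rf$importance, raw_importance = rf$raw,
                 oob_mse = rf$oob_mse, moran = mi,
                 residuals_independent = indep,
                 seed = spec$seed, spec = spec),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("importance_report:", x$response, "| seed", x$seed, "\n")
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("dropped:", paste(sprintf("%s(%s)", x$dropped$predictor,
                                  x$dropped$reason), collapse = ", "), "\n")
  }
  print(round(sort(x$importance, decreasing = TRUE), 2))
  cat("residuals spatially independent:", x$residuals_independent, "\n")
  invisible(x)
}
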