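#' Fit a latitudinal gradient by ordinary least squares
#'
#' Fits \code{y ~ lat} (linear) or \code{y ~ lat + lat^2} (quadratic).
#' Richness responses are conventionally analysed on the natural-log scale
#' (set \code{log_y = TRUE}; zero or negative values are then dropped with a
#' recorded count, mirroring presence-only species lists); mean root distance
#' is analysed raw.
#'
#' @param y Numeric response, one value per reserve.
#' @param lat Latitudes in decimal degrees.
#' @param shape \code{"linear"} or \code{"quadratic"}.
#' @param log_y Natural-log transform the response before fitting?
#' @param response,predictor Optional names recorded in the result.
#' @return A \code{"gradient_fit"} list: coefficients (\code{intercept},
#'   \code{b} for lat, \code{a} for lat^2 when quadratic), \code{r_squared},
#'   \code{p_value} (overall F test), \code{n}, \code{lat_range},
#'   \code{n_dropped_log}.
#' @export
fit_latitudinal <- function(y, lat, shape = c("linear", "quadratic"),
                            log_y = FALSE, response = "y", predictor = "lat") {
  shape <- match.arg(shape)
  keep <- is.finite(y) & is.finite(lat)
  n_dropped_log <- 0L
  if (log_y) {
    pos <- keep & y > 0
    n_dropped_log <- sum(keep & !pos)
    keep <- pos
  }
  y <- if (log_y) log(y[keep]) else y[keep]
  lat <- lat[keep]
  n_min <- if (shape == "linear") 3L else 4L
  if (length(y) < n_min) {
    stop("need at least ", n_min, " complete cases for a ", shape, " fit",
         call. = FALSE)
  }
  if (stats::var(lat) == 0) stop("latitude has zero variance", call. = FALSE)
  if (stats::var(y) == 0) {
    # constant response: a gradient-free null fit (slope 0, R^2 0) keeps
    # degenerate simulations (e.g. saturated occupancy) comparable
    coefs <- c(intercept = mean(y), b = 0,
               if (shape == "quadratic") c(a = 0))
    fit <- list(response = response, predictor = predictor, shape = shape,
                coefficients = coefs, r_squared = 0, p_value = 1,
                n = length(y), lat_range = range(lat),
                n_dropped_log = n_dropped_log, log_y = log_y)
    class(fit) <- "gradient_fit"
    return(fit)
  }
  df <- data.frame(y = y, lat = lat)
  mod <- if (shape == "linear") {
    stats::lm(y ~ lat, data = df)
  } else {
    stats::lm(y ~ lat + I(lat^2), data = df)
  }
  sm <- summary(mod)
  fstat <- sm$fstatistic
  pval <- if (is.null(fstat)) 1 else
    unname(stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  cf <- stats::coef(mod)
  coefs <- c(intercept = unname(cf[1L]), b = unname(cf[2L]))
  if (shape == "quadratic") coefs <- c(coefs, a = unname(cf[3L]))
  fit <- list(response = response, predictor = predictor, shape = shape,
              coefficients = coefs, r_squared = sm$r.squared,
              p_value = pval, n = length(y), lat_range = range(lat),
              n_dropped_log = n_dropped_log, log_y = log_y)
  class(fit) <- "gradient_fit"
  fit
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("gradient_fit: %s ~ %s (%s), n = %d, R2 = %.3f, p = %.3g\n",
              x$response, x$predictor, x$shape, x$n, x$r_squared, x$p_value))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Peak latitude of a concave quadratic gradient
#'
#' The vertex of the fitted parabola, -b / (2a). A peak is reported only when
#' the quadratic opens downward (a < 0) and the vertex falls inside the
#' latitude range of the fitted data; otherwise \code{NA} with a reason.
#'
#' @param fit A quadratic \code{"gradient_fit"}.
#' @return A list with \code{peak} (degrees, or \code{NA}) and \code{reason}.
#' @export
peak_latitude <- function(fit) {
  stopifnot(inherits(fit, "gradient_fit"))
  if (fit$shape != "quadratic") {
    stop("peak_latitude requires a quadratic fit", call. = FALSE)
  }
  a <- fit$coefficients[["a"]]
  b <- fit$coefficients[["b"]]
  if (a == 0) return(list(peak = NA_real_, reason = "degenerate quadratic"))
  if (a > 0) return(list(peak = NA_real_, reason = "upward parabola"))
  peak <- -b / (2 * a)
  if (peak < fit$lat_range[1L] || peak > fit$lat_range[2L]) {
    return(list(peak = NA_real_, reason = "vertex outside data range"))
  }
  list(peak = peak, reason = "ok")
}

#' Significance codes for p-values
#'
#' \code{ns} for p >= .1, a single quote mark for p < .1, then \code{*},
#' \code{**}, \code{***} at .05, .01, .001.
#'
#' @param p Numeric p-values.
#' @return Character vector of codes.
#' @export
sig_code <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", "'", "ns"), right = FALSE) |>
    as.character()
}

#' Bivariate variance-explained table
#'
#' For every predictor x response pair, the percentage of variance explained
#' (100 R^2) by a single-predictor OLS, with a significance code and a flag
#' for the three strongest predictors per response. Richness responses are
#' natural-log transformed; \code{AREA}, when present among the predictors,
#' is entered as its natural log and labelled \code{Ln(AREA)}.
#'
#' @param covariates Data.frame of per-reserve predictors.
#' @param responses Data.frame of per-reserve responses (same row order).
#' @param predictors Character vector of predictor column names (default: all
#'   numeric columns of \code{covariates}).
#' @param log_responses Character vector naming which responses are
#'   log-transformed before fitting (richness-type responses).
#' @return A data.frame with one row per predictor x response:
#'   \code{predictor}, \code{response}, \code{r2_pct}, \code{p_value},
#'   \code{code}, \code{top3}, \code{n}.
#' @export
bivariate_table <- function(covariates, responses,
                            predictors = NULL, log_responses = character(0)) {
  if (is.null(predictors)) {
    predictors <- names(covariates)[vapply(covariates, is.numeric, logical(1L))]
  }
  missing_p <- setdiff(predictors, names(covariates))
  if (length(missing_p)) {
    stop("predictor(s) not in covariates: ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (resp in names(responses)) {
    y0 <- responses[[resp]]
    logged <- resp %in% log_responses
    for (pred in predictors) {
      x0 <- covariates[[pred]]
      label <- pred
      if (pred == "AREA") {
        x0 <- log(x0)
        label <- "Ln(AREA)"
      }
      keep <- is.finite(x0) & is.finite(y0)
      if (logged) keep <- keep & y0 > 0
      x <- x0[keep]
      y <- if (logged) log(y0[keep]) else y0[keep]
      if (length(y) < 3L || all(!is.finite(x)) ||
          stats::var(x) == 0 || stats::var(y) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          predictor = label, response = resp, r2_pct = NA_real_,
          p_value = NA_real_, code = "unavailable", top3 = FALSE,
          n = length(y), stringsAsFactors = FALSE)
        next
      }
      sm <- summary(stats::lm(y ~ x))
      f <- sm$fstatistic
      p <- unname(stats::pf(f[1L], f[2L], f[3L], lower.tail = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = label, response = resp, r2_pct = 100 * sm$r.squared,
        p_value = p, code = sig_code(p), top3 = FALSE, n = length(y),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  for (resp in unique(out$response)) {
    i <- which(out$response == resp & is.finite(out$r2_pct))
    top <- i[order(out$r2_pct[i], decreasing = TRUE)][seq_len(min(3L, length(i)))]
    out$top3[top] <- TRUE
  }
  rownames(out) <- NULL
  out
}
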