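#' Construct a grid layer
#'
#' A minimal in-memory raster: a numeric matrix (rows = north to south, as in
#' ESRI ASCII grids), a cell size, an origin, and a no-data sentinel. Cells
#' equal to the sentinel are treated as missing everywhere.
#'
#' @param values Numeric matrix.
#' @param cellsize Positive cell edge length.
#' @param xll,yll Lower-left corner coordinates.
#' @param nodata No-data sentinel value (default -9999).
#' @return An object of class \code{"grid_layer"}.
#' @export
grid_layer <- function(values, cellsize = 1, xll = 0, yll = 0, nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || cellsize <= 0) {
    stop("'cellsize' must be positive", call. = FALSE)
  }
  structure(list(values = values, cellsize = cellsize,
                 xll = xll, yll = yll, nodata = nodata),
            class = "grid_layer")
}

grid_values <- function(g) {
  v <- g$values
  v[v == g$nodata] <- NA_real_
  v
}

#' @export
print.grid_layer <- function(x, ...) {
  cat("grid_layer:", nrow(x$values), "x", ncol(x$values),
      "cells, cellsize", x$cellsize, "\n")
  invisible(x)
}

#' Topographic roughness from slope
#'
#' TR = 1 / cos(slope in radians), a per-cell terrain heterogeneity index:
#' the ratio of true surface area to its planimetric projection. TR is 1 on
#' flat ground and increases without bound as slope approaches 90 degrees.
#' Full machine-precision pi is used.
#'
#' @param slope_deg Slope in degrees, in \[0, 90).
#' @return TR values (>= 1), same shape as the input.
#' @examples
#' topographic_roughness(60)  # exactly 2
#' @export
topographic_roughness <- function(slope_deg) {
  if (any(!is.finite(slope_deg)) || any(slope_deg < 0) || any(slope_deg >= 90)) {
    stop("slope must lie in [0, 90) degrees", call. = FALSE)
  }
  1 / cos(slope_deg * pi / 180)
}

#' Per-cell slope (degrees) from a DEM, Horn's 3x3 method
#'
#' The east-west and north-south gradients are estimated with Horn's weighted
#' finite differences over each cell's 3x3 neighbourhood; slope is
#' atan(|grad|). Cells beyond the border are filled by edge replication, and
#' no-data neighbours are replaced by the centre cell's value, so every valid
#' centre cell receives a slope.
#'
#' @param dem A [grid_layer()] of elevations with at least 3x3 cells.
#' @return A [grid_layer()] of slope in degrees (no-data where the DEM is).
#' @export
slope_from_dem <- function(dem) {
  stopifnot(inherits(dem, "grid_layer"))
  z <- grid_values(dem)
  if (nrow(z) < 3L || ncol(z) < 3L) {
    stop("DEM must be at least 3x3 cells", call. = FALSE)
  }
  nr <- nrow(z); nc <- ncol(z)
  # edge replication via clamped index shifts
  up <- z[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- z[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  shift <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    m[ri, ci, drop = FALSE]
  }
  nb <- list(
    nw = shift(z, -1L, -1L), n = shift(z, -1L, 0L), ne = shift(z, -1L, 1L),
    w  = shift(z,  0L, -1L),                        e  = shift(z,  0L, 1L),
    sw = shift(z,  1L, -1L), s = shift(z,  1L, 0L), se = shift(z,  1L, 1L)
  )
  nb <- lapply(nb, function(m) {
    m[is.na(m)] <- z[is.na(m)]  # no-data neighbour -> centre value
    m
  })
  cs <- dem$cellsize
  gx <- ((nb$ne + 2 * nb$e + nb$se) - (nb$nw + 2 * nb$w + nb$sw)) / (8 * cs)
  gy <- ((nb$sw + 2 * nb$s + nb$se) - (nb$nw + 2 * nb$n + nb$ne)) / (8 * cs)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  slope[is.na(z)] <- dem$nodata
  slope[is.na(slope)] <- dem$nodata
  grid_layer(slope, cellsize = cs, xll = dem$xll, yll = dem$yll,
             nodata = dem$nodata)
}

#' Monthly climate container
#'
#' Twelve monthly mean temperatures (degrees C) and twelve monthly
#' precipitation totals (mm), either as length-12 numeric vectors (one
#' location) or as 12-column matrices (rows = locations/cells).
#'
#' @param temp,precip Length-12 vectors or n x 12 matrices.
#' @param era \code{"current"} or \code{"LGM"}.
#' @return An object of class \code{"monthly_climate"}.
#' @export
monthly_climate <- function(temp, precip, era = c("current", "LGM")) {
  era <- match.arg(era)
  to_mat <- function(x, nm) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    x <- as.matrix(x)
    if (ncol(x) != 12L) stop("'", nm, "' must have 12 monthly values", call. = FALSE)
    x
  }
  temp <- to_mat(temp, "temp")
  precip <- to_mat(precip, "precip")
  if (nrow(temp) != nrow(precip)) {
    stop("'temp' and 'precip' row counts differ", call. = FALSE)
  }
  if (any(precip < 0, na.rm = TRUE)) {
    stop("precipitation must be non-negative", call. = FALSE)
  }
  structure(list(temp = temp, precip = precip, era = era),
            class = "monthly_climate")
}

#' Climate indices from monthly data
#'
#' MAT is the mean of the 12 monthly temperatures; MAP the sum of the 12
#' monthly precipitation values (the WorldClim convention); MTCM the minimum
#' monthly temperature, a surrogate for absolute winter minimum.
#'
#' @param mc A [monthly_climate()].
#' @return A data.frame with one row per location: \code{MAT}, \code{MAP},
#'   \code{MTCM}.
#' @export
climate_indices <- function(mc) {
  stopifnot(inherits(mc, "monthly_climate"))
  data.frame(MAT = rowMeans(mc$temp),
             MAP = rowSums(mc$precip),
             MTCM = apply(mc$temp, 1L, min))
}

#' Glacial-interglacial temperature anomaly
#'
#' T_Anomaly = current mean annual temperature minus Last Glacial Maximum
#' mean annual temperature; positive values mean warming since the LGM.
#'
#' @param current,lgm [monthly_climate()] objects for the two eras.
#' @return Numeric vector of anomalies, one per location.
#' @export
climate_anomaly <- function(current, lgm) {
  stopifnot(inherits(current, "monthly_climate"), inherits(lgm, "monthly_climate"))
  climate_indices(current)$MAT - climate_indices(lgm)$MAT
}

#' Annual NDVI by monthly maximum-value compositing
#'
#' Within each month, the per-cell maximum over that month's dekadal (~10-day)
#' layers suppresses cloud contamination; the annual per-cell value is the
#' mean of the 12 monthly composites; the reserve scalar is the mean over
#' valid cells and, when several years are supplied, over years.
#'
#' @param dekads For one year: a list of 12 elements, each a list of one or
#'   more numeric matrices (dekadal NDVI layers of identical shape). For
#'   several years: a list of such year-lists.
#' @return A list with \code{scalar} (the reserve-level NDVI) and
#'   \code{annual} (the per-cell annual matrix, averaged over years).
#' @export
ndvi_annual <- function(dekads) {
  is_year <- function(y) is.list(y) && length(y) == 12L
  years <- if (is_year(dekads)) list(dekads) else dekads
  if (!length(years) || !all(vapply(years, is_year, logical(1L)))) {
    stop("'dekads' must be one, or a list of, 12-month dekad lists", call. = FALSE)
  }
  annual_one <- function(year) {
    monthly <- vector("list", 12L)
    for (m in seq_len(12L)) {
      layers <- year[[m]]
      if (is.matrix(layers) || is.numeric(layers)) layers <- list(layers)
      if (!length(layers)) {
        stop("month ", m, " has no dekadal layers", call. = FALSE)
      }
      monthly[[m]] <- Reduce(pmax, lapply(layers, as.matrix))
    }
    Reduce(`+`, monthly) / 12
  }
  per_year <- lapply(years, annual_one)
  annual <- Reduce(`+`, per_year) / length(per_year)
  list(scalar = mean(annual, na.rm = TRUE), annual = annual)
}

#' Aggregate a grid layer to a reserve-level scalar
#'
#' Arithmetic mean over valid (non-missing, non-sentinel) cells.
#'
#' @param layer A [grid_layer()].
#' @return A single number.
#' @export
aggregate_reserve <- function(layer) {
  stopifnot(inherits(layer, "grid_layer"))
  v <- grid_values(layer)
  if (!any(is.finite(v))) stop("no valid cells to aggregate", call. = FALSE)
  mean(v, na.rm = TRUE)
}

#' Monthly Thornthwaite potential evapotranspiration (helper)
#'
#' A simple temperature-based PET estimate. This helper is provided for
#' convenience when no PET layer is available; pipelines that have a PET
#' product should supply it directly as a per-reserve input instead.
#'
#' @param temp12 Length-12 vector of monthly mean temperatures (degrees C).
#' @return Annual PET in mm.
#' @export
pet_thornthwaite <- function(temp12) {
  if (length(temp12) != 12L) stop("'temp12' must have 12 values", call. = FALSE)
  tpos <- pmax(temp12, 0)
  I <- sum((tpos / 5)^1.514)
  if (I == 0) return(0)
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  sum(16 * (10 * tpos / I)^a)
}
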