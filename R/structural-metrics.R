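# Per-survey structural metrics (HH_cv, FC, d_D) and their seasonal
# stability (inverse coefficient of variation across surveys).

#' Digital canopy model
#'
#' Rasterizes a normalized cloud to cell-wise maximum height at the given
#' resolution. Cells containing no points are missing (NA), not zero:
#' zero-filling would conflate canopy gaps with height variance.
#'
#' @param cloud normalized \code{point_cloud}.
#' @param resolution_m cell size in meters (default 0.1).
#' @return numeric matrix of cell heights with NA for empty cells.
#' @export
canopy_model <- function(cloud, resolution_m = 0.1) {
  if (nrow(cloud) == 0) stopf("empty cloud")
  x0 <- min(cloud$x); y0 <- min(cloud$y)
  ix <- as.integer(floor((cloud$x - x0) / resolution_m + 1e-9)) + 1L
  iy <- as.integer(floor((cloud$y - y0) / resolution_m + 1e-9)) + 1L
  dt <- data.table(ix = ix, iy = iy, z = cloud$z)
  mx <- dt[, list(h = max(z)), by = c("ix", "iy")]
  grid <- matrix(NA_real_, max(ix), max(iy))
  grid[cbind(mx$ix, mx$iy)] <- mx$h
  grid
}

#' Canopy height heterogeneity (HH_cv)
#'
#' Coefficient of variation (sample sd / mean) of the non-empty cells of a
#' 0.1 m digital canopy model.
#'
#' @param cloud normalized \code{point_cloud}.
#' @param resolution_m DCM cell size in meters.
#' @return dimensionless CV.
#' @export
canopy_height_cv <- function(cloud, resolution_m = 0.1) {
  h <- canopy_model(cloud, resolution_m)
  h <- h[!is.na(h)]
  if (length(h) < 2) stopf("need at least two non-empty canopy cells")
  if (mean(h) <= 0) stopf("degenerate plot: mean canopy height is not positive")
  cv(h)
}

#' Fractional plant cover (FC)
#'
#' Sum of inverse return numbers over vegetation returns (height above
#' \code{z_min}) divided by the number of pulses. Pulses are identified by
#' \code{return_number == 1} when no pulse ids are available. A first return
#' from vegetation contributes 1 pulse fully intercepted; a second return
#' contributes 1/2, and so on, so FC lies in [0, 1].
#'
#' @param cloud normalized \code{point_cloud}.
#' @param z_min vegetation height threshold in meters (default 0.25).
#' @return cover fraction in [0, 1].
#' @export
fractional_cover <- function(cloud, z_min = 0.25) {
  n_pulses <- sum(cloud$return_number == 1L)
  if (n_pulses == 0) stopf("no first returns: cannot count pulses")
  veg <- cloud$z > z_min
  fc <- sum(1 / cloud$return_number[veg]) / n_pulses
  if (fc > 1) {
    warnf("inverse-return-number weighting exceeded 1 (%.4f); clamping", fc)
    fc <- 1
  }
  fc
}

#' Hill diversity of order q
#'
#' \eqn{{}^qD = (\sum_i p_i^q)^{1/(1-q)}} with the Shannon limit
#' \eqn{\exp(-\sum p_i \log p_i)} taken when \eqn{|q-1| < 10^{-6}}.
#' Proportions are normalized internally and zero entries ignored; q = 0
#' returns richness, q = 2 the inverse Simpson concentration.
#'
#' @param p nonnegative proportions (normalized internally).
#' @param q Hill order, q >= 0.
#' @return effective number, >= 1.
#' @export
hill_diversity <- function(p, q) {
  if (length(p) == 0) stopf("empty proportion vector")
  if (any(p < 0)) stopf("proportions must be nonnegative")
  p <- p[p > 0]
  if (length(p) == 0) stopf("all proportions are zero")
  p <- p / sum(p)
  if (abs(q - 1) < 1e-6) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

#' Default box-counting scale sequence
#'
#' Twelve log-spaced voxel edge sizes spanning 0.1 m to 2.25 m, the range
#' over which the log-log scaling is close to linear for plot-scale clouds.
#'
#' @param n number of scales.
#' @param s_min,s_max edge-size range in meters.
#' @return numeric vector of edge sizes, increasing.
#' @export
default_scales <- function(n = 12, s_min = 0.1, s_max = 2.25) {
  exp(seq(log(s_min), log(s_max), length.out = n))
}

#' Box-counting Hill-diversity curve
#'
#' For each voxel edge size, assigns points to voxels anchored at the cloud
#' minimum corner, forms the proportion of points per occupied voxel, and
#' evaluates Hill diversity of order \code{q}. At q = 0 this is classic box
#' counting (occupied-voxel count).
#'
#' @param cloud \code{point_cloud}.
#' @param scales voxel edge sizes in meters.
#' @param q Hill order.
#' @return data.frame with columns \code{scale} and \code{diversity}.
#' @export
box_counting_curve <- function(cloud, scales = default_scales(), q = 0.999) {
  if (nrow(cloud) == 0) stopf("empty cloud")
  if (any(scales <= 0)) stopf("scales must be positive")
  origin <- c(min(cloud$x), min(cloud$y), min(cloud$z))
  D <- vapply(scales, function(s) {
    idx <- voxel_index(cloud$x, cloud$y, cloud$z, s, origin)
    counts <- idx[, .N, by = c("ix", "iy", "iz")]$N
    hill_diversity(counts / sum(counts), q)
  }, numeric(1))
  out <- data.frame(scale = scales, diversity = D)
  attr(out, "q") <- q
  out
}

#' Standardized major axis (SMA) fit
#'
#' Symmetric line fit used for log-log scaling relationships:
#' slope = sign(r) * sd(y)/sd(x), intercept = mean(y) - slope * mean(x).
#' When y has zero variance the slope is 0 and the fit is flagged degenerate
#' (uniform diversity across scales).
#'
#' @param x,y numeric vectors, length >= 3.
#' @return list with \code{slope}, \code{intercept}, \code{r},
#'   \code{degenerate}.
#' @export
sma_fit <- function(x, y) {
  if (length(x) < 3 || length(y) != length(x))
    stopf("need >= 3 paired points")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0) stopf("zero variance in x")
  if (sy == 0)
    return(list(slope = 0, intercept = mean(y), r = NA_real_,
                degenerate = TRUE))
  r <- stats::cor(x, y)
  slope <- sign(r) * sy / sx
  if (slope == 0) slope <- sy / sx  # r == 0: orientation undefined, keep +
  list(slope = slope, intercept = mean(y) - slope * mean(x), r = r,
       degenerate = FALSE)
}

#' Box-counting fractal dimension d_D
#'
#' SMA slope of log Hill diversity against log(1/S) over the scale sequence.
#' Near-1 orders (default q = 0.999) weight voxels by occupancy and damp the
#' influence of point-density differences among plots; q = 0 reduces to the
#' classic box-counting dimension.
#'
#' @param cloud \code{point_cloud}.
#' @param q Hill order (default 0.999).
#' @param scales voxel edge sequence (default \code{default_scales()}).
#' @return the dimension estimate (slope), dimensionless.
#' @export
fractal_dimension <- function(cloud, q = 0.999, scales = default_scales()) {
  curve <- box_counting_curve(cloud, scales = scales, q = q)
  sma_fit(log(1 / curve$scale), log(curve$diversity))$slope
}

#' Seasonal structural stability (SS)
#'
#' Inverse coefficient of variation, mean / sample sd, of a metric across
#' repeated surveys in one growing season. Computed only on complete series;
#' zero variance yields +Inf flagged as perfectly stable.
#'
#' @param values metric values, one per survey; no missing values allowed.
#' @return stability (dimensionless), possibly \code{Inf} with attribute
#'   \code{perfectly_stable = TRUE}.
#' @export
structural_stability <- function(values) {
  if (length(values) < 2) stopf("need at least two surveys")
  if (any(!is.finite(values)))
    stopf("incomplete series: stability requires every survey")
  s <- stats::sd(values)
  if (s == 0) {
    out <- Inf
    attr(out, "perfectly_stable") <- TRUE
    return(out)
  }
  mean(values) / s
}

#' Plot inclusion rule for seasonal analyses
#'
#' A plot enters the seasonal analyses only if its canopy (max DCM cell
#' height) exceeds 1.5 m at every survey, its mean planting year is before
#' 2019, and it was not replanted in the productivity interval.
#'
#' @param max_heights per-survey maximum canopy height (m), complete series.
#' @param planting_years per-tree planting years for the plot.
#' @param replanted logical replanted flag.
#' @param min_height height rule in meters (default 1.5).
#' @param max_year latest acceptable mean planting year (exclusive,
#'   default 2019).
#' @return logical keep flag.
#' @export
plot_inclusion_filter <- function(max_heights, planting_years,
                                  replanted = FALSE,
                                  min_height = 1.5, max_year = 2019) {
  if (any(!is.finite(max_heights))) stopf("incomplete height series")
  all(max_heights > min_height) &&
    mean(planting_years) < max_year &&
    !isTRUE(replanted)
}

#' Structural metric series for one plot
#'
#' Convenience wrapper: computes HH_cv, FC and d_D for each conditioned
#' survey cloud of a plot.
#'
#' @param clouds list of conditioned \code{point_cloud}s, one per survey.
#' @param doys survey days of year, parallel to \code{clouds}.
#' @param q,scales passed to \code{\link{fractal_dimension}}.
#' @return data.frame with columns doy, hh_cv, fc, d_D, max_height.
#' @export
metric_series <- function(clouds, doys, q = 0.999, scales = default_scales()) {
  stopifnot(length(clouds) == length(doys))
  rows <- lapply(seq_along(clouds), function(i) {
    cl <- clouds[[i]]
    data.frame(doy = doys[i],
               hh_cv = canopy_height_cv(cl),
               fc = fractional_cover(cl),
               d_D = fractal_dimension(cl, q = q, scales = scales),
               max_height = max(cl$z))
  })
  do.call(rbind, rows)
}
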