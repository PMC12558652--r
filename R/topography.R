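# Spatial statistics: tonotopic gradient fits, best-frequency heterogeneity
# at field / local / nearest-neighbour scales, area assignment.

#' Project positions onto the tonotopic axis
#'
#' Scalar projection of map-frame positions (µm) onto the caudal-to-rostral
#' unit vector, origin at the low-frequency-area centroid, reported in mm.
#'
#' @param xy_um matrix or data.frame with two columns (x, y in µm), or a
#'   length-2 vector.
#' @param axis list with `origin_um` (length-2) and `direction` (unit
#'   vector), as produced by [locate_areas()].
#' @return numeric vector of axis positions in mm.
#' @export
project_to_axis <- function(xy_um, axis) {
  stop_if(is.null(axis) || is.null(axis$direction), "missing tonotopic axis")
  xy <- if (is.null(dim(xy_um))) matrix(xy_um, ncol = 2) else as.matrix(xy_um)
  d <- axis$direction / sqrt(sum(axis$direction^2))
  as.numeric((sweep(xy, 2, axis$origin_um) %*% d) / 1000)
}

#' Fit the tonotopic gradient
#'
#' Ordinary least squares of log2(BF / 2 kHz) on axis position, with Pearson
#' correlation and its two-sided t-approximation p value.  The slope is in
#' octaves/mm.
#'
#' @param axis_mm axis positions (mm).
#' @param bf_khz best frequencies (kHz).
#' @return list of class `gradient_fit`: `slope_oct_per_mm`, `intercept_oct`,
#'   `pearson_r`, `p_value`, `n`, `degenerate` (TRUE when the BFs carry no
#'   variance).
#' @export
fit_gradient <- function(axis_mm, bf_khz) {
  keep <- is.finite(axis_mm) & is.finite(bf_khz)
  x <- axis_mm[keep]; y <- khz_to_oct(bf_khz[keep])
  stop_if(length(x) < 3, "need at least 3 tuned points")
  stop_if(stats::var(x) == 0, "zero variance in positions")
  if (stats::var(y) == 0) {
    return(structure(list(slope_oct_per_mm = 0, intercept_oct = y[1],
                          pearson_r = 0, p_value = NA_real_, n = length(x),
                          degenerate = TRUE), class = "gradient_fit"))
  }
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(slope_oct_per_mm = unname(stats::coef(fit)[2]),
                 intercept_oct = unname(stats::coef(fit)[1]),
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x), degenerate = FALSE),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("Tonotopic gradient: %.2f oct/mm, R = %.3f, p = %.3g, n = %d%s\n",
              x$slope_oct_per_mm, x$pearson_r, x$p_value, x$n,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Field-scale best-frequency interquartile range
#'
#' IQR (75th - 25th percentile, linear interpolation) of the tuned neurons'
#' best frequencies in octaves over a focal plane.  Returned missing unless
#' at least `min_neurons` tuned neurons lie within `radius_um` of the field
#' center (center neuron included).
#'
#' @param x_um,y_um tuned-neuron coordinates within the field (µm).
#' @param bf_khz their best frequencies (kHz).
#' @param center_um field center; defaults to the field midpoint (mean of
#'   coordinates).
#' @param radius_um counting radius (µm).
#' @param min_neurons minimum tuned-neuron count within the radius.
#' @return IQR in octaves, or NA.
#' @export
field_iqr <- function(x_um, y_um, bf_khz, center_um = NULL, radius_um = 100,
                      min_neurons = 5) {
  keep <- is.finite(bf_khz)
  x <- x_um[keep]; y <- y_um[keep]; bf <- bf_khz[keep]
  if (length(bf) == 0) return(NA_real_)
  if (is.null(center_um)) center_um <- c(mean(x), mean(y))
  d <- sqrt((x - center_um[1])^2 + (y - center_um[2])^2)
  if (sum(d <= radius_um) < min_neurons) return(NA_real_)
  iqr_oct(khz_to_oct(bf))
}

#' Local best-frequency interquartile range
#'
#' Samples tuned neurons as centers (without replacement, seeded) and
#' computes the IQR of the best frequencies of all tuned neurons within
#' `radius_um` of each center (center included), keeping a sample only when
#' at least `min_neighbors` neurons fall inside the radius.
#'
#' @param x_um,y_um,bf_khz tuned neurons in one plane.
#' @param radius_um neighbourhood radius (µm).
#' @param n_centers centers sampled (default: all tuned neurons, capped at 40).
#' @param min_neighbors minimum neuron count (center included) to retain a
#'   sample.
#' @param seed integer seed for the center sampling.
#' @return data.frame with `center_x_um`, `center_y_um`, `n_in_radius`,
#'   `iqr_oct` (zero rows if nothing retained).
#' @export
local_iqr <- function(x_um, y_um, bf_khz, radius_um = 25, n_centers = NULL,
                      min_neighbors = 3, seed = 1) {
  keep <- is.finite(bf_khz)
  x <- x_um[keep]; y <- y_um[keep]; bf_oct <- khz_to_oct(bf_khz[keep])
  n <- length(x)
  stop_if(n < 1, "need at least one tuned neuron")
  if (is.null(n_centers)) n_centers <- min(n, 40L)
  set.seed(seed)
  centers <- sample.int(n, min(n_centers, n))
  rows <- lapply(centers, function(i) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    inr <- which(d <= radius_um)
    if (length(inr) < min_neighbors) return(NULL)
    data.frame(center_x_um = x[i], center_y_um = y[i],
               n_in_radius = length(inr), iqr_oct = iqr_oct(bf_oct[inr]))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows)) do.call(rbind, rows)
  else data.frame(center_x_um = numeric(), center_y_um = numeric(),
                  n_in_radius = integer(), iqr_oct = numeric())
}

#' Nearest-neighbour best-frequency differences
#'
#' For every tuned neuron, the absolute octave difference between its best
#' frequency and that of its Euclidean-nearest tuned neighbour in the same
#' plane (distance ties broken by lower neuron index).
#'
#' @param x_um,y_um,bf_khz tuned neurons in one plane.
#' @return numeric vector of octave differences (one per neuron; empty when
#'   fewer than 2 tuned neurons).
#' @export
nn_delta_frequency <- function(x_um, y_um, bf_khz) {
  keep <- is.finite(bf_khz)
  x <- x_um[keep]; y <- y_um[keep]; bf_oct <- khz_to_oct(bf_khz[keep])
  n <- length(x)
  if (n < 2) return(numeric(0))
  vapply(seq_len(n), function(i) {
    d <- (x - x[i])^2 + (y - y[i])^2
    d[i] <- Inf
    abs(bf_oct[i] - bf_oct[which.min(d)])
  }, numeric(1))
}

#' Assign a field of view to the LF / HF area
#'
#' Labels a field-of-view center by membership in the wide-field area masks
#' (boundary pixels inclusive).
#'
#' @param center_um length-2 field center in map-frame µm.
#' @param masks list with `lf` and `hf` logical matrices (map frame).
#' @param um_per_px microns per downsampled map pixel.
#' @return `"LF"`, `"HF"` or `"other"`.
#' @export
assign_area <- function(center_um, masks, um_per_px) {
  px <- pmax(1L, round(center_um / um_per_px))
  r <- px[2]; cl <- px[1]   # x -> column, y -> row
  dims <- dim(masks$lf)
  stop_if(!all(dim(masks$hf) == dims), "LF / HF mask frame mismatch")
  if (r > dims[1] || cl > dims[2]) return("other")
  if (masks$lf[r, cl]) return("LF")
  if (masks$hf[r, cl]) return("HF")
  "other"
}
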