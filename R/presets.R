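# Synthetic population presets ("TR" / "CT") and the calibration of the
# best-frequency scatter model that underlies them.
#
# The generator draws, for each tuned neuron, a latent octave value
#   y* = intercept + slope_latent * axis_mm + N(0, sigma_latent),
# clamps it to the 2-40 kHz grid range and (for neuron-level sampling) snaps
# it to the nearest protocol tone.  Clamping and snapping attenuate both the
# realized OLS slope and the Pearson R relative to the latent line, so the
# latent (slope, sigma) are calibrated numerically - via closed-form moments
# of the censored / quantized normal - such that the *measured* population
# slope and R equal the preset targets.

# Moments of snap(clamp(N(mu, sigma))) onto grid values g (octaves).
# mu may be a vector.  Returns E[Y] and E[Y^2].
.snap_moments <- function(mu, sigma, grid_oct) {
  b <- (grid_oct[-1] + grid_oct[-length(grid_oct)]) / 2   # snap boundaries
  # P(Y = g_k) via differences of the normal CDF at the boundaries
  cdf <- vapply(b, function(bk) stats::pnorm((bk - mu) / sigma),
                numeric(length(mu)))                      # n_mu x n_bounds
  if (is.null(dim(cdf))) cdf <- matrix(cdf, nrow = length(mu))
  cdf <- cbind(0, cdf, 1)
  p <- cdf[, -1, drop = FALSE] - cdf[, -ncol(cdf), drop = FALSE]
  list(m1 = as.numeric(p %*% grid_oct),
       m2 = as.numeric(p %*% grid_oct^2))
}

# Moments of clamp(N(mu, sigma), L, U) (censored normal).
.censor_moments <- function(mu, sigma, L, U) {
  a <- (L - mu) / sigma
  b <- (U - mu) / sigma
  Fa <- stats::pnorm(a); Fb <- stats::pnorm(b)
  fa <- stats::dnorm(a); fb <- stats::dnorm(b)
  m1 <- L * Fa + U * (1 - Fb) + mu * (Fb - Fa) - sigma * (fb - fa)
  # E[(mu + sigma Z)^2 ; a<Z<b] expanded in truncated-normal moments
  i0 <- Fb - Fa
  i1 <- fa - fb
  i2 <- (Fb - b * fb) - (Fa - a * fa)
  m2 <- L^2 * Fa + U^2 * (1 - Fb) +
    mu^2 * i0 + 2 * mu * sigma * i1 + sigma^2 * i2
  list(m1 = m1, m2 = m2)
}

# Population-level OLS slope and Pearson R of the generated BF (octaves)
# against axis position, for latent parameters, by quadrature over positions
# uniform on [0, extent].
.measured_gradient <- function(slope_latent, sigma_latent, extent_mm,
                               grid_oct, snap = TRUE, n_nodes = 401) {
  xs <- (seq_len(n_nodes) - 0.5) * extent_mm / n_nodes
  center <- (min(grid_oct) + max(grid_oct)) / 2
  mu <- center + slope_latent * (xs - extent_mm / 2)
  mo <- if (snap) .snap_moments(mu, sigma_latent, grid_oct)
        else .censor_moments(mu, sigma_latent, min(grid_oct), max(grid_oct))
  mx <- mean(xs); vx <- mean((xs - mx)^2)
  my <- mean(mo$m1)
  cov_xy <- mean((xs - mx) * mo$m1)
  var_y <- mean(mo$m2) - my^2
  slope <- cov_xy / vx
  r <- cov_xy / sqrt(vx * var_y)
  list(slope = slope, r = r, sd_y = sqrt(var_y), intercept = my - slope * mx)
}

#' Calibrate the latent best-frequency scatter model of a gradient preset
#'
#' Finds latent slope and scatter such that the measured ordinary-least-squares
#' slope (octaves/mm) and Pearson R of generated best frequencies against
#' tonotopic-axis position equal the requested targets, accounting for
#' clamping to the tone-grid range and (optionally) snapping to the grid.
#' The variance-decomposition closed form
#' `sigma = |slope| * SD(pos) * sqrt(1/R^2 - 1)` is used as the starting
#' point.
#'
#' @param target_slope target measured slope, octaves/mm.
#' @param target_r target measured Pearson R.
#' @param extent_mm axis extent (positions uniform on `[0, extent_mm]`).
#' @param grid_oct tone grid in octaves re 2 kHz.
#' @param snap whether generated values are snapped to the grid.
#' @return list with `slope_latent`, `sigma_latent`, `intercept_latent`,
#'   and `achieved` (measured slope / R at the solution).
#' @export
calibrate_bf_scatter <- function(target_slope, target_r, extent_mm = 1.2,
                                 grid_oct = khz_to_oct(2 * 20^(0:10 / 10)),
                                 snap = TRUE) {
  stop_if(target_slope <= 0 || target_r <= 0 || target_r >= 1,
          "targets must satisfy slope > 0, 0 < R < 1")
  sd_x <- extent_mm / sqrt(12)
  sigma0 <- target_slope * sd_x * sqrt(1 / target_r^2 - 1)
  obj <- function(par) {
    g <- .measured_gradient(par[1], exp(par[2]), extent_mm, grid_oct, snap)
    ((g$slope - target_slope) / target_slope)^2 + ((g$r - target_r) / target_r)^2
  }
  fit <- stats::optim(c(target_slope, log(sigma0)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  sl <- fit$par[1]; sg <- exp(fit$par[2])
  g <- .measured_gradient(sl, sg, extent_mm, grid_oct, snap)
  list(slope_latent = sl, sigma_latent = sg,
       latent_intercept = (min(grid_oct) + max(grid_oct)) / 2 - sl * extent_mm / 2,
       achieved = list(slope = g$slope, r = g$r, sd_y = g$sd_y),
       converged = fit$convergence == 0)
}

# Expected sample median of n_draws per-plane best frequencies whose latent
# values are N(mu, w), clamped to the grid range and snapped to the grid.
# Exact through order statistics of the discrete snapped distribution.
.plane_median_expect <- function(mu, w, grid_oct, n_draws) {
  b <- (grid_oct[-1] + grid_oct[-length(grid_oct)]) / 2
  cdf <- vapply(b, function(bk) stats::pnorm((bk - mu) / w),
                numeric(length(mu)))
  if (is.null(dim(cdf))) cdf <- matrix(cdf, nrow = length(mu))
  cdf <- cbind(cdf, 1)
  e_order <- function(k) {
    # P(X_(k) <= g_j) = P(Binom(n, F_j) >= k)
    ple <- 1 - stats::pbinom(k - 1, n_draws, cdf)
    pmf <- cbind(ple[, 1, drop = FALSE],
                 ple[, -1, drop = FALSE] - ple[, -ncol(ple), drop = FALSE])
    as.numeric(pmf %*% grid_oct)
  }
  if (n_draws %% 2 == 1) e_order((n_draws + 1) / 2)
  else (e_order(n_draws / 2) + e_order(n_draws / 2 + 1)) / 2
}

# Latent plane-level slope such that the expected OLS slope of per-plane
# median BFs against plane position equals the target, given plane scatter
# sigma_plane and within-plane scatter w with n_draws neurons per plane.
.calibrate_plane_slope <- function(target_slope, sigma_plane, w, n_draws,
                                   extent_mm, grid_oct, n_nodes = 201) {
  xs <- (seq_len(n_nodes) - 0.5) * extent_mm / n_nodes
  center <- (min(grid_oct) + max(grid_oct)) / 2
  # plane-noise quadrature
  eps <- seq(-4, 4, length.out = 33)
  wts <- stats::dnorm(eps); wts <- wts / sum(wts)
  meas_slope <- function(sl) {
    mu0 <- center + sl * (xs - extent_mm / 2)
    em <- numeric(length(xs))
    for (i in seq_along(eps)) {
      mu <- clamp(mu0 + eps[i] * sigma_plane, min(grid_oct), max(grid_oct))
      em <- em + wts[i] * .plane_median_expect(mu, w, grid_oct, n_draws)
    }
    mx <- mean(xs)
    sum((xs - mx) * em) / sum((xs - mx)^2)
  }
  sl <- target_slope
  for (it in 1:4) {
    m <- meas_slope(sl)
    if (abs(m - target_slope) < 1e-4) break
    sl <- sl * target_slope / max(m, 1e-6)
  }
  sl
}

.preset_cache <- new.env(parent = emptyenv())

#' Load a synthetic-population preset
#'
#' Presets bundle the generating parameters of the two study populations:
#' `"TR"` (thalamocortical-recipient-like: tonotopic, narrowly tuned) and
#' `"CT"` (corticothalamic-like: non-tonotopic, broadly tuned).  Parameter
#' values live in `inst/extdata/presets.yaml`; the latent gradient models
#' (neuron- and plane-level) are calibrated on first use and cached.
#'
#' @param name `"TR"` or `"CT"`.
#' @param file optional path to a YAML preset file (defaults to the bundled one).
#' @return A list of class `synth_preset`.
#' @export
synth_preset <- function(name = c("TR", "CT"), file = NULL) {
  name <- match.arg(name)
  key <- paste0(name, "::", if (is.null(file)) "builtin" else file)
  if (!is.null(.preset_cache[[key]])) return(.preset_cache[[key]])
  if (is.null(file))
    file <- system.file("extdata", "presets.yaml", package = "tonotopr",
                        mustWork = TRUE)
  all <- yaml::read_yaml(file)
  p <- utils::modifyList(all$common, all[[name]])
  p$name <- name
  cf <- unlist(p$class_fractions)
  stop_if(abs(sum(cf) - 1) > 1e-9, "class fractions must sum to 1")
  sf <- unlist(p$shape_fractions)
  stop_if(abs(sum(sf) - 1) > 1e-9, "shape fractions must sum to 1")
  stop_if(abs(sum(unlist(p$bwmax_step_probs)) - 1) > 1e-9,
          "bwmax_step_probs must sum to 1")
  grid_oct <- khz_to_oct(2 * 20^(0:10 / 10))
  p$grid_oct <- grid_oct
  p$gradient$neuron$latent <- calibrate_bf_scatter(
    p$gradient$neuron$slope_oct_per_mm, p$gradient$neuron$pearson_r,
    p$axis_extent_mm, grid_oct, snap = TRUE)
  p$gradient$plane$latent <- calibrate_bf_scatter(
    p$gradient$plane$slope_oct_per_mm, p$gradient$plane$pearson_r,
    p$axis_extent_mm, grid_oct, snap = FALSE)
  # plane scatter deflated by the sampling noise of the within-plane median,
  # and the latent plane slope corrected for the attenuation that clamping
  # to the grid range induces in finite-sample medians
  lat <- p$gradient$plane$latent
  w <- p$within_plane_sd_oct
  med_var <- (pi / 2) * (w^2 + GRID_STEP_OCT^2 / 12) / p$tuned_per_plane
  lat$sigma_plane_adj <- sqrt(max(lat$sigma_latent^2 - med_var, 1e-4))
  lat$slope_plane_adj <- .calibrate_plane_slope(
    p$gradient$plane$slope_oct_per_mm, lat$sigma_plane_adj, w,
    p$tuned_per_plane, p$axis_extent_mm, grid_oct)
  p$gradient$plane$latent <- lat
  class(p) <- "synth_preset"
  .preset_cache[[key]] <- p
  p
}

#' @export
print.synth_preset <- function(x, ...) {
  cat(sprintf("Synthetic preset '%s': tuned/irregular/silent = %s\n", x$name,
              paste(unlist(x$class_fractions), collapse = "/")))
  cat(sprintf("  neuron gradient target %.2f oct/mm (R %.3f); plane target %.2f oct/mm (R %.2f)\n",
              x$gradient$neuron$slope_oct_per_mm, x$gradient$neuron$pearson_r,
              x$gradient$plane$slope_oct_per_mm, x$gradient$plane$pearson_r))
  invisible(x)
}
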