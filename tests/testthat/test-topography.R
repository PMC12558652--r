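test_that("axis projection is linear, origin-anchored and sign-flips", {
  axis <- list(origin_um = c(1000, 500), direction = c(1, 0))
  expect_equal(project_to_axis(c(1000, 500), axis), 0)
  expect_equal(project_to_axis(c(1500, 500), axis), 0.5)
  rev_axis <- list(origin_um = c(1000, 500), direction = c(-1, 0))
  pts <- cbind(runif(10, 0, 3000), runif(10, 0, 1000))
  expect_equal(project_to_axis(pts, rev_axis),
               -project_to_axis(pts, axis))
  expect_error(project_to_axis(c(0, 0), NULL), "missing")
})

test_that("gradient fit recovers a noiseless line and flags degeneracy", {
  x <- seq(0, 1.2, length.out = 20)
  bf <- oct_to_khz(0.5 + 2 * x)
  f <- fit_gradient(x, bf)
  expect_equal(f$slope_oct_per_mm, 2, tolerance = 1e-9)
  expect_equal(f$pearson_r, 1, tolerance = 1e-9)
  fd <- fit_gradient(x, rep(8, 20))
  expect_true(fd$degenerate)
  expect_equal(fd$slope_oct_per_mm, 0)
  expect_error(fit_gradient(rep(0.5, 10), bf[1:10]), "zero variance")
  expect_error(fit_gradient(x[1:2], bf[1:2]), "at least 3")
})

test_that("gradient fit matches the closed-form two-point slope", {
  # three points, two distinct positions: slope equals rise over run of means
  x <- c(0, 0, 1)
  bf <- oct_to_khz(c(0.4, 0.6, 1.5))
  f <- fit_gradient(x, bf)
  expect_equal(f$slope_oct_per_mm, 1.5 - 0.5, tolerance = 1e-9)
})

test_that("field IQR follows the percentile convention and the 5-neuron rule", {
  bf <- oct_to_khz(c(0, 0.43, 0.86, 1.29, 1.72))
  x <- c(50, 60, 70, 80, 90); y <- rep(50, 5)
  expect_equal(field_iqr(x, y, bf, center_um = c(70, 50)), 0.86)
  # only 4 tuned neurons within 100 um: missing
  expect_true(is.na(field_iqr(x[1:4], y[1:4], bf[1:4], center_um = c(65, 50))))
  expect_equal(field_iqr(x, y, rep(8, 5), center_um = c(70, 50)), 0)
})

test_that("field and local IQR agree with a sort-based percentile oracle", {
  oracle_iqr <- function(v) {
    s <- sort(v); n <- length(s)
    q <- function(p) {
      h <- (n - 1) * p + 1
      lo <- floor(h); hi <- ceiling(h)
      s[lo] + (h - lo) * (s[hi] - s[lo])
    }
    q(0.75) - q(0.25)
  }
  set.seed(31)
  for (k in 1:20) {
    bf_oct <- sample(seq(0, 4.32, by = 0.432), sample(5:30, 1), replace = TRUE)
    got <- field_iqr(seq_along(bf_oct), rep(0, length(bf_oct)),
                     oct_to_khz(bf_oct), center_um = c(0, 0),
                     radius_um = 1e6)
    expect_equal(got, oracle_iqr(bf_oct), tolerance = 1e-12)
  }
})

test_that("local IQR retains only centers with enough neighbours", {
  # isolated neuron: nothing retained
  out <- local_iqr(c(0, 500), c(0, 0), c(4, 8), radius_um = 25)
  expect_equal(nrow(out), 0)
  # homogeneous cluster: IQR 0
  out2 <- local_iqr(c(0, 5, 10, 15), rep(0, 4), rep(8, 4), radius_um = 25)
  expect_true(all(out2$iqr_oct == 0))
  expect_gt(nrow(out2), 0)
})

test_that("nearest-neighbour deltas match a brute-force all-pairs oracle", {
  set.seed(8)
  n <- 50
  x <- runif(n, 0, 200); y <- runif(n, 0, 200)
  bf <- oct_to_khz(sample(seq(0, 4.32, by = 0.432), n, replace = TRUE))
  got <- nn_delta_frequency(x, y, bf)
  d2 <- as.matrix(dist(cbind(x, y)))^2
  diag(d2) <- Inf
  want <- vapply(seq_len(n), function(i) {
    j <- which.min(d2[i, ])       # which.min takes the lowest index on ties
    abs(khz_to_oct(bf[i]) - khz_to_oct(bf[j]))
  }, numeric(1))
  expect_equal(got, want)
  # trivial cases
  expect_equal(nn_delta_frequency(c(0, 10), c(0, 0), c(8, 8)), c(0, 0))
  expect_equal(nn_delta_frequency(c(0, 10), c(0, 0), c(4, 8)), c(1, 1))
  expect_equal(length(nn_delta_frequency(1, 1, 8)), 0)
})

test_that("within-plane heterogeneity orders TR below CT across seeds", {
  # focal planes carry the within-plane BF scatter; compare the pooled
  # local IQR and nearest-neighbour deltas across planes per seed
  wins_local <- 0; wins_nn <- 0
  for (s in 1:10) {
    stat <- lapply(c("TR", "CT"), function(nm) {
      sp <- sample_planes(synth_preset(nm), seed = s)
      li <- nn <- numeric(0)
      for (pl in unique(sp$neurons$plane)) {
        nr <- sp$neurons[sp$neurons$plane == pl, ]
        li <- c(li, local_iqr(nr$x_um, nr$y_um, nr$bf_khz, seed = pl)$iqr_oct)
        nn <- c(nn, nn_delta_frequency(nr$x_um, nr$y_um, nr$bf_khz))
      }
      c(local = median(li), nn = median(nn))
    })
    wins_local <- wins_local + (stat[[1]]["local"] < stat[[2]]["local"])
    wins_nn <- wins_nn + (stat[[1]]["nn"] < stat[[2]]["nn"])
  }
  expect_gte(wins_local, 9)
  expect_gte(wins_nn, 9)
})

test_that("area assignment is by mask membership, boundary inclusive", {
  lf <- matrix(FALSE, 10, 10); lf[3:5, 2:4] <- TRUE
  hf <- matrix(FALSE, 10, 10); hf[3:5, 7:9] <- TRUE
  masks <- list(lf = lf, hf = hf)
  expect_equal(assign_area(c(3, 4) * 100, masks, um_per_px = 100), "LF")
  expect_equal(assign_area(c(8, 4) * 100, masks, um_per_px = 100), "HF")
  expect_equal(assign_area(c(5.5, 1) * 100, masks, um_per_px = 100), "other")
  # boundary pixel of the LF mask
  expect_equal(assign_area(c(2, 3) * 100, masks, um_per_px = 100), "LF")
})
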