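# Internal helpers shared across modules.

# Octave spacing of the standard 11-tone 2-40 kHz grid: log2(40/2)/10.
GRID_STEP_OCT <- log2(20) / 10

#' Convert frequency in kHz to octaves above 2 kHz
#' @param f_khz frequencies in kHz
#' @return octaves re 2 kHz
#' @export
khz_to_oct <- function(f_khz) log2(f_khz / 2)

#' Convert octaves above 2 kHz to frequency in kHz
#' @param oct octaves re 2 kHz
#' @return frequency in kHz
#' @export
oct_to_khz <- function(oct) 2 * 2^oct

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# Shared percentile convention: linear interpolation between order statistics
# (quantile type 7).  Every IQR / percentile in the package goes through this.
pctl <- function(x, probs) stats::quantile(x, probs = probs, type = 7, names = FALSE)

iqr_oct <- function(bf_oct) {
  q <- pctl(bf_oct, c(0.25, 0.75))
  q[2] - q[1]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Rolling standard deviation with a centered window (length w samples).
# Edge windows are truncated.  Used to set transient detection noise levels.
rolling_sd <- function(x, w) {
  n <- length(x)
  if (w >= n) return(rep(stats::sd(x), n))
  half <- floor(w / 2)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- hi - lo + 1
  s <- cs[hi + 1] - cs[lo]
  s2 <- cs2[hi + 1] - cs2[lo]
  v <- (s2 - s^2 / cnt) / (cnt - 1)
  sqrt(pmax(v, 0))
}

# Exponential (single-pole IIR) smoothing, time constant tau_s seconds.
ema_filter <- function(x, fs_hz, tau_s) {
  a <- 1 - exp(-1 / (fs_hz * tau_s))
  as.numeric(stats::filter(a * x, 1 - a, method = "recursive", init = x[1]))
}

# Label connected components of a logical matrix.  connectivity 4 or 8.
# Tiny flood fill; operates on FRA grids (11 x 6) and downsampled wide-field
# masks, so no performance concern.
label_components <- function(mask, connectivity = 4) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- rep(c(-1L, 0L, 1L), 3L); dc <- rep(c(-1L, 0L, 1L), each = 3L)
    keep <- !(dr == 0L & dc == 0L); dr <- dr[keep]; dc <- dc[keep]
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- cur
    while (nrow(stack) > 0) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (k in seq_along(dr)) {
        ii <- p[1] + dr[k]; jj <- p[2] + dc[k]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack <- rbind(stack, c(ii, jj))
        }
      }
    }
  }
  lab
}

# Block-average a matrix by an integer factor along both axes.
block_mean <- function(m, factor) {
  nr <- nrow(m); nc <- ncol(m)
  stop_if(nr %% factor != 0, "row dimension (", nr, ") not divisible by ", factor)
  stop_if(nc %% factor != 0, "column dimension (", nc, ") not divisible by ", factor)
  nr2 <- nr %/% factor; nc2 <- nc %/% factor
  dim(m) <- c(factor, nr2, factor, nc2)
  out <- apply(m, c(2, 4), mean)
  matrix(out, nr2, nc2)
}

# Separable box filter with reflect padding.
box_filter <- function(m, k) {
  stopifnot(k %% 2 == 1)
  if (k == 1) return(m)
  half <- (k - 1) / 2
  pad_idx <- function(n) c(rev(seq_len(half) + 1L), seq_len(n), n - seq_len(half))
  mp <- m[pad_idx(nrow(m)), pad_idx(ncol(m)), drop = FALSE]
  roll <- function(v, k) {
    cs <- c(0, cumsum(v))
    (cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]) / k
  }
  tmp <- apply(mp, 2, roll, k = k)          # (nrow(m)) x ncol(mp)
  out <- t(apply(tmp, 1, roll, k = k))      # nrow(m) x ncol(m)
  matrix(out, nrow(m), ncol(m))
}

# Seed helper: deterministic child seeds below 2^31 derived from a base seed.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483629)
}
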