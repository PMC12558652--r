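# Two-photon movie preprocessing: rigid motion correction, ROI trace
# extraction, df/f conversion.

.translate_int <- function(frame, dy, dx, fill) {
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- frame[src_r[ok_r], src_c[ok_c]]
  out
}

.ssd_best_shift <- function(frame, template, max_shift) {
  best <- c(0L, 0L); best_ssd <- Inf
  nr <- nrow(frame); nc <- ncol(frame)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    r1 <- max(1, 1 + dy):min(nr, nr + dy)
    c1 <- max(1, 1 + dx):min(nc, nc + dx)
    r0 <- r1 - dy; c0 <- c1 - dx
    d <- frame[r0, c0] - template[r1, c1]
    ssd <- sum(d * d) / length(d)      # per-pixel SSD: overlap-size invariant
    if (ssd < best_ssd - 1e-12) { best_ssd <- ssd; best <- c(dy, dx) }
  }
  list(shift = best, ssd = best_ssd)
}

#' Rigid motion correction by SSD template matching
#'
#' For each frame, finds the integer (dy, dx) translation within
#' `±max_shift_px` minimizing the mean squared intensity difference against a
#' template, then applies the shift.  The template is the mean of the first
#' `template_frames` frames; one refinement pass recomputes it from the
#' corrected movie and re-estimates the shifts.  Vacated edges are filled
#' with the template border median.
#'
#' @param movie 3-D array (rows x cols x frames).
#' @param max_shift_px maximum search radius in pixels.
#' @param template_frames number of leading frames averaged for the initial
#'   template.
#' @param refine run the refinement pass (default TRUE).
#' @return list with `shifts` (frames x 2 matrix, columns dy, dx),
#'   `corrected` (array like `movie`) and `template`.
#' @export
motion_correct <- function(movie, max_shift_px = 6, template_frames = 100,
                           refine = TRUE) {
  stopifnot(length(dim(movie)) == 3)
  nf <- dim(movie)[3]
  stop_if(nf < 2, "movie must have at least 2 frames")
  stop_if(max_shift_px < 0, "max_shift_px must be >= 0")
  stop_if(max_shift_px > min(dim(movie)[1:2]) / 2,
          "max_shift_px larger than half the frame")

  run_pass <- function(template) {
    border <- c(template[1, ], template[nrow(template), ],
                template[, 1], template[, ncol(template)])
    fill <- stats::median(border)
    shifts <- matrix(0L, nf, 2, dimnames = list(NULL, c("dy", "dx")))
    corrected <- movie
    for (k in seq_len(nf)) {
      bs <- .ssd_best_shift(movie[, , k], template, max_shift_px)
      sh <- bs$shift    # correction shift: the negation of the frame's motion
      shifts[k, ] <- sh
      corrected[, , k] <- .translate_int(movie[, , k], sh[1], sh[2], fill)
    }
    list(shifts = shifts, corrected = corrected, template = template)
  }

  template <- apply(movie[, , seq_len(min(template_frames, nf)), drop = FALSE],
                    c(1, 2), mean)
  pass <- run_pass(template)
  if (refine) {
    template2 <- apply(pass$corrected, c(1, 2), mean)
    pass <- run_pass(template2)
  }
  pass
}

#' Extract raw ROI traces from a movie
#'
#' Per-frame mean of the pixel values inside each ROI.  No neuropil
#' subtraction is applied.
#'
#' @param movie 3-D array (rows x cols x frames).
#' @param rois integer label matrix (0 = background) matching the frame size.
#' @return matrix frames x ROIs; column names are the ROI labels.
#' @export
extract_traces <- function(movie, rois) {
  stopifnot(length(dim(movie)) == 3, is.matrix(rois))
  stop_if(!all(dim(rois) == dim(movie)[1:2]), "ROI mask / frame size mismatch")
  labels <- sort(setdiff(unique(as.integer(rois)), 0L))
  stop_if(length(labels) == 0, "no ROIs in mask")
  nf <- dim(movie)[3]
  flat <- matrix(movie, nrow = prod(dim(movie)[1:2]), ncol = nf)
  out <- matrix(NA_real_, nf, length(labels))
  for (k in seq_along(labels)) {
    px <- which(as.integer(rois) == labels[k])
    stop_if(length(px) == 0, "empty ROI label ", labels[k])
    out[, k] <- colMeans(flat[px, , drop = FALSE])
  }
  colnames(out) <- labels
  out
}

#' Compute df/f from a raw fluorescence trace
#'
#' `df/f = (f - f0) / f0` with the baseline `f0` estimated as the 25th
#' percentile of the entire recording (linear-interpolation percentile).
#'
#' @param raw_trace numeric vector of raw fluorescence.
#' @param fs_hz sampling rate, stored on the result.
#' @param baseline_rule `"percentile25"` (default) or `"prestim_mean"`; for
#'   the latter supply `prestim_frames`.
#' @param prestim_frames frames averaged when `baseline_rule = "prestim_mean"`.
#' @return object of class `dff_trace`: list with `values`, `fs_hz`, `f0`,
#'   `baseline_rule`.
#' @export
compute_dff <- function(raw_trace, fs_hz = 30,
                        baseline_rule = c("percentile25", "prestim_mean"),
                        prestim_frames = NULL) {
  baseline_rule <- match.arg(baseline_rule)
  stop_if(length(raw_trace) == 0, "empty trace")
  f0 <- if (baseline_rule == "percentile25") pctl(raw_trace, 0.25)
  else mean(raw_trace[seq_len(prestim_frames)])
  stop_if(f0 <= 0,
          "baseline f0 <= 0; offset-correct the raw trace before df/f")
  structure(list(values = (raw_trace - f0) / f0, fs_hz = fs_hz, f0 = f0,
                 baseline_rule = baseline_rule),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("df/f trace: %d frames at %g Hz, f0 = %.4g (%s)\n",
              length(x$values), x$fs_hz, x$f0, x$baseline_rule))
  invisible(x)
}
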