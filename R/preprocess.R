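#' Amplitude-threshold artifact detection
#'
#' Flags every sample deviating from the block mean by more than
#' `threshold_sd` standard deviations. Eye and muscle artifacts at a
#' frontal electrode are much larger than resting EEG, so a simple 4.5
#' sigma rule isolates them. The standard deviation is computed once on
#' the raw block, artifacts included (a two-pass robust variant, which
#' re-estimates sigma after excluding flagged samples, is available via
#' `robust = TRUE`).
#'
#' @param block an [eeg_block()] or numeric vector with at least 2 samples.
#' @param threshold_sd detection threshold in standard deviations.
#' @param robust if `TRUE`, re-estimate mean/sd once with initially flagged
#'   samples excluded and re-apply the threshold.
#' @return An object of class `"artifact_mask"`: a logical vector (`TRUE` =
#'   artifact) with a `segments` attribute, a data.frame of the contiguous
#'   flagged runs (`start`, `end`, 1-based inclusive).
#' @examples
#' x <- rnorm(1000)
#' x[500] <- 12
#' which(detect_artifacts(x))
#' @export
detect_artifacts <- function(block, threshold_sd = 4.5, robust = FALSE) {
  x <- as.numeric(block)
  stopifnot(length(x) >= 2L, threshold_sd > 0)
  s <- stats::sd(x)
  if (s == 0) {
    warning("constant block: zero variance, no artifacts flaggable")
    return(new_artifact_mask(rep(FALSE, length(x))))
  }
  flags <- abs(x - mean(x)) > threshold_sd * s
  if (robust && any(flags)) {
    clean <- x[!flags]
    s2 <- stats::sd(clean)
    if (s2 > 0) flags <- abs(x - mean(clean)) > threshold_sd * s2
  }
  new_artifact_mask(flags)
}

new_artifact_mask <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  structure(flags, segments = seg, class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  seg <- attr(x, "segments")
  cat(sprintf("<artifact_mask> %d/%d samples flagged in %d segment(s)\n",
              sum(x), length(x), nrow(seg)))
  if (nrow(seg)) print(utils::head(seg, 10))
  invisible(x)
}

#' Clean a block: iterated artifact detection and spectral repair
#'
#' Alternates [detect_artifacts()] and [fft_interpolate()] until no
#' sample exceeds the threshold (or `max_passes` is reached). A single
#' pass can leave the shoulders of a smooth artifact just above
#' threshold, because repairing the peak shrinks the block's standard
#' deviation; one or two further passes reach a fixed point.
#'
#' Each detected run is grown outward (hysteresis) while neighbouring
#' samples stay above `hysteresis_sd` standard deviations, so the whole
#' transient is replaced rather than just its peak — otherwise the
#' interpolant is pulled back up by the artifact's shoulders.
#'
#' @param block an [eeg_block()] or numeric vector.
#' @param threshold_sd detection threshold in standard deviations.
#' @param robust use the two-pass robust sigma estimate in detection.
#' @param hysteresis_sd lower threshold to which flagged runs are grown.
#' @param max_passes cap on detect/repair rounds.
#' @return The cleaned block, with attributes `n_passes` and
#'   `n_repaired` (total samples replaced).
#' @export
clean_block <- function(block, threshold_sd = 4.5, robust = TRUE,
                        hysteresis_sd = 3, max_passes = 5) {
  out <- block
  total <- 0L
  passes <- 0L
  for (i in seq_len(max_passes)) {
    mask <- suppressWarnings(detect_artifacts(out, threshold_sd, robust))
    if (!any(mask)) break
    x <- as.numeric(out)
    z <- abs(x - mean(x)) / stats::sd(x)
    flags <- as.logical(mask)
    seg <- attr(mask, "segments")
    for (r in seq_len(nrow(seg))) {
      lo <- seg$start[r]
      while (lo > 1 && z[lo - 1] > hysteresis_sd) lo <- lo - 1
      hi <- seg$end[r]
      while (hi < length(z) && z[hi + 1] > hysteresis_sd) hi <- hi + 1
      flags[lo:hi] <- TRUE
    }
    out <- fft_interpolate(out, flags)
    total <- total + sum(flags)
    passes <- passes + 1L
  }
  attr(out, "n_passes") <- passes
  attr(out, "n_repaired") <- total
  out
}

#' Spectral (FFT) interpolation of artifact gaps
#'
#' Reconstructs flagged samples from the discrete Fourier representation
#' of the surrounding clean data. Gaps are initialised by linear
#' interpolation, then the signal is iteratively projected onto its `K`
#' strongest Fourier components with known samples restored after each
#' pass, until the change on gap samples falls below a relative tolerance
#' or the iteration cap is hit. `K` is chosen so the retained components
#' carry 95% of the initialised signal's spectral power, which keeps the
#' broadband character of the clean data while suppressing the transient.
#'
#' Unflagged samples are returned bit-identical to the input.
#'
#' @param block an [eeg_block()] or numeric vector.
#' @param mask logical vector from [detect_artifacts()] (same length).
#' @param power_frac fraction of spectral power the retained components
#'   must carry (sets `K`).
#' @param tol relative convergence tolerance on the gap samples.
#' @param max_iter iteration cap.
#' @return A repaired block of the same class and length as the input.
#' @examples
#' t <- seq(0, 4, by = 1 / 125)
#' x <- sin(2 * pi * 10 * t)
#' m <- rep(FALSE, length(x)); m[200:219] <- TRUE
#' y <- fft_interpolate(x, m)
#' max(abs(y[200:219] - x[200:219]))
#' @export
fft_interpolate <- function(block, mask, power_frac = 0.95, tol = 1e-6,
                            max_iter = 100) {
  x <- as.numeric(block)
  mask <- as.logical(mask)
  stopifnot(length(mask) == length(x))
  frac <- mean(mask)
  if (frac >= 0.5)
    stop(sprintf("block unusable: %.0f%% of samples flagged (>= 50%%)",
                 100 * frac))
  if (!any(mask)) return(block)
  n <- length(x)
  idx <- seq_len(n)
  good <- which(!mask)
  # initialise gaps by linear interpolation (rule = 2 handles edge gaps)
  y <- x
  y[mask] <- stats::approx(good, x[good], xout = which(mask), rule = 2)$y
  # K strongest components of the initialised signal carrying power_frac of
  # its power (DC always kept; components counted as conjugate pairs)
  sp <- Mod(stats::fft(y))^2
  ord <- order(sp, decreasing = TRUE)
  cum <- cumsum(sp[ord])
  K <- which(cum >= power_frac * sum(sp))[1]
  keep <- ord[seq_len(max(K, 1L))]
  # include conjugate partners so the inverse transform stays real
  conj_idx <- ifelse(keep == 1L, 1L, n - keep + 2L)
  keep <- union(keep, conj_idx)
  gap <- which(mask)
  for (iter in seq_len(max_iter)) {
    X <- stats::fft(y)
    Xf <- complex(real = rep(0, n), imaginary = rep(0, n))
    Xf[keep] <- X[keep]
    y_new <- Re(stats::fft(Xf, inverse = TRUE)) / n
    delta <- sqrt(mean((y_new[gap] - y[gap])^2))
    scale <- sqrt(mean(y[gap]^2)) + 1e-12
    y[gap] <- y_new[gap]  # known samples stay fixed
    if (delta / scale < tol) break
  }
  out <- x
  out[gap] <- y[gap]
  if (inherits(block, "eeg_block")) block_like(out, block) else out
}
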