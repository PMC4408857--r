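#' The seven EEG frequency bands
#'
#' Band edges in Hz: lower delta (1--2), upper delta (2--4), theta (4--8),
#' alpha (8--13), lower beta (13--20), upper beta (20--30), gamma
#' (30--60). Bands are half-open `[lo, hi)` except gamma, which includes
#' its upper edge (the hardware band limit).
#'
#' @return A data.frame with columns `name`, `lo`, `hi`.
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("lower_delta", "upper_delta", "theta", "alpha", "lower_beta",
             "upper_beta", "gamma"),
    lo = c(1, 2, 4, 8, 13, 20, 30),
    hi = c(2, 4, 8, 13, 20, 30, 60))
}

# Welch-averaged one-sided periodogram: Hann window, 50% overlap by default.
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  n <- length(x)
  L <- round(window_s * fs)
  if (n < L) stop("block shorter than one analysis window")
  step <- max(1L, round(L * (1 - overlap)))
  w <- 0.5 * (1 - cos(2 * pi * seq.int(0, L - 1) / L))
  starts <- seq.int(1L, n - L + 1L, by = step)
  acc <- numeric(L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  p <- acc / (length(starts) * sum(w^2) * fs)
  nf <- floor(L / 2) + 1L
  psd <- p[seq_len(nf)]
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]  # fold negative frequencies
  list(freq = (seq_len(nf) - 1L) * fs / L, psd = psd)
}

#' Fractional band powers from a windowed FFT
#'
#' Averaged windowed periodogram (Hann window, 50% overlap), integrated
#' over each band and returned as fractions of the total 1--60 Hz power.
#' The 2-s default window gives 0.5 Hz resolution, enough to resolve the
#' 1-Hz-wide lower-delta band.
#'
#' @param block an [eeg_block()] or numeric vector.
#' @param fs sampling rate (Hz); taken from the block if available.
#' @param bands band table as from [eeg_bands()].
#' @param window_s analysis window length (s).
#' @param overlap window overlap fraction.
#' @return Named numeric vector of 7 band fractions summing to 1.
#' @examples
#' t <- seq(0, 40, by = 1 / 125)[-1]
#' band_powers(sin(2 * pi * 10 * t), fs = 125)  # all power in alpha
#' @export
band_powers <- function(block, fs = NULL, bands = eeg_bands(),
                        window_s = 2, overlap = 0.5) {
  x <- as.numeric(block)
  if (is.null(fs)) fs <- attr(block, "fs")
  stopifnot(!is.null(fs), fs >= 2 * max(bands$hi) * 0.999)
  pw <- welch_psd(x, fs, window_s, overlap)
  in_total <- pw$freq >= min(bands$lo) & pw$freq <= max(bands$hi)
  total <- sum(pw$psd[in_total])
  if (total <= 0) stop("no spectral power in the analysis range")
  out <- vapply(seq_len(nrow(bands)), function(i) {
    hi_closed <- bands$hi[i] == max(bands$hi)  # top band includes its edge
    sel <- pw$freq >= bands$lo[i] &
      (if (hi_closed) pw$freq <= bands$hi[i] else pw$freq < bands$hi[i])
    sum(pw$psd[sel]) / total
  }, numeric(1))
  stats::setNames(out, bands$name)
}

#' Binned Shannon entropy of the amplitude distribution
#'
#' Histograms the samples into `n_bins` uniform bins spanning the data
#' range and returns `-sum(p * log(p))` over non-empty bins, in nats.
#' The maximum attainable value is `log(n_bins)`. One value is computed
#' for the whole block.
#'
#' @param block an [eeg_block()] or numeric vector.
#' @param n_bins number of uniform histogram bins.
#' @return Entropy in nats; 0 (with a warning) for a constant block.
#' @examples
#' shannon_entropy(rep(seq(0.5, 9.5), 100) / 10)  # fills 10 bins: log(10)
#' @export
shannon_entropy <- function(block, n_bins = 10) {
  x <- as.numeric(block)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant block: Shannon entropy 0 by convention")
    return(0)
  }
  bin <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
  p <- tabulate(bin, nbins = n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Sample entropy
#'
#' Negative natural log of the conditional probability that template
#' vectors matching for `m` points remain within tolerance `r` for `m + 1`
#' points. Matches use the Euclidean distance between delayed vectors
#' `[x(i), ..., x(i + m - 1)]` by default (`metric = "chebyshev"` gives the
#' max-norm convention common elsewhere, for cross-checks). The tolerance
#' is `r_factor` times the block standard deviation. Pair counts at length
#' `m` run over templates `i = 1..N-m` and at length `m + 1` over
#' `i = 1..N-m-1`, each normalised by the corresponding
#' `(N-m)(N-m-1)`-type factor before the ratio is taken.
#'
#' The counting core is exact: it returns the same integer pair counts as
#' a literal O(N^2) double loop.
#'
#' @param block an [eeg_block()] or numeric vector.
#' @param m template (run) length.
#' @param r_factor tolerance as a multiple of the block SD.
#' @param metric `"euclidean"` (default) or `"chebyshev"`.
#' @return Non-negative real; `Inf` if no template pair matches at length
#'   `m + 1`.
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(500))
#' @export
sample_entropy <- function(block, m = 2, r_factor = 0.25,
                           metric = c("euclidean", "chebyshev")) {
  x <- as.numeric(block)
  metric <- match.arg(metric)
  n <- length(x)
  stopifnot(m >= 1, n > m + 1, r_factor > 0)
  s <- stats::sd(x)
  if (s == 0) stop("constant block: sample entropy undefined (sigma = 0)")
  r <- r_factor * s
  cnt <- .sampen_counts_cpp(x, as.integer(m), r, metric == "chebyshev")
  um <- 2 * cnt[1] / ((n - m) * (n - m - 1))
  um1 <- 2 * cnt[2] / ((n - m - 1) * (n - m - 2))
  if (cnt[1] == 0) {
    warning("no template matches at length m; sample entropy undefined")
    return(Inf)
  }
  if (cnt[2] == 0) {
    warning("no template matches at length m + 1; returning Inf")
    return(Inf)
  }
  -log(um1 / um)
}

#' Full feature vector of a block
#'
#' Normalises the block to unit standard deviation, then computes the
#' seven fractional band powers, the binned Shannon entropy and the sample
#' entropy. All three families are scale-invariant by construction (bins
#' span the data range, the sample-entropy tolerance is proportional to
#' sigma, band powers are fractions), so pre-scaling the input has no
#' effect.
#'
#' @param block an [eeg_block()] or numeric vector.
#' @param fs sampling rate; taken from the block if available.
#' @param n_bins Shannon histogram bins.
#' @param m,r_factor sample-entropy settings (see [sample_entropy()]).
#' @param window_s,overlap band-power window settings.
#' @return An object of class `"feature_vector"`: a list with elements
#'   `band_powers` (named length-7), `shannon`, `sampen`.
#' @examples
#' fv <- feature_vector(simulate_oscillator(reference_params("EC-CTL"),
#'                                          duration = 8, seed = 1))
#' fv
#' @export
feature_vector <- function(block, fs = NULL, n_bins = 10, m = 2,
                           r_factor = 0.25, window_s = 2, overlap = 0.5) {
  x <- as.numeric(block)
  if (is.null(fs)) fs <- attr(block, "fs")
  if (is.null(fs)) fs <- 125
  s <- stats::sd(x)
  if (s == 0) stop("constant block: features undefined")
  x <- x / s
  structure(list(
    band_powers = band_powers(x, fs = fs, window_s = window_s,
                              overlap = overlap),
    shannon = shannon_entropy(x, n_bins = n_bins),
    sampen = sample_entropy(x, m = m, r_factor = r_factor)),
    class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, digits = 4, ...) {
  cat("<feature_vector>\n band powers (fraction of 1-60 Hz):\n")
  print(round(x$band_powers, digits))
  cat(sprintf(" Shannon entropy: %.*f nats\n sample entropy:  %.*f\n",
              digits, x$shannon, digits, x$sampen))
  invisible(x)
}

# Element-wise mean of a list of feature vectors.
average_features <- function(fvs) {
  structure(list(
    band_powers = rowMeans(vapply(fvs, `[[`, numeric(7), "band_powers")),
    shannon = mean(vapply(fvs, `[[`, numeric(1), "shannon")),
    sampen = mean(vapply(fvs, `[[`, numeric(1), "sampen"))),
    class = "feature_vector")
}

as_feature_vector <- function(x) {
  if (inherits(x, "feature_vector")) return(x)
  stopifnot(is.list(x), all(c("band_powers", "shannon", "sampen") %in%
                              names(x)))
  structure(list(band_powers = unlist(x$band_powers), shannon = x$shannon,
                 sampen = x$sampen), class = "feature_vector")
}
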