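#' Average mutual information profile
#'
#' Mutual information (in bits) between the series and its lagged copy,
#' for lags `0..t_max`. Joint probabilities come from a `n_bins` x
#' `n_bins` histogram over uniform bins spanning the series range (the
#' same bin edges at every lag); zero-count cells contribute nothing.
#' `I(0)` equals the binned marginal entropy.
#'
#' @param series numeric vector (or [eeg_block()]); length must be at
#'   least `10 * t_max`.
#' @param t_max largest lag, in samples.
#' @param n_bins histogram bins per axis.
#' @return An object of class `"ami_profile"`: data.frame with columns
#'   `lag` and `ami` (bits).
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 40, by = 1 / 125))
#' prof <- average_mutual_information(x, t_max = 20)
#' select_delay(prof)
#' @export
average_mutual_information <- function(series, t_max = 50, n_bins = 20) {
  x <- as.numeric(series)
  n <- length(x)
  stopifnot(t_max >= 1, n >= 10 * t_max)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant series: zero mutual information at all lags")
    return(structure(data.frame(lag = 0:t_max, ami = 0),
                     class = c("ami_profile", "data.frame")))
  }
  bin <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
  ami <- vapply(0:t_max, function(T) {
    a <- bin[seq_len(n - T)]
    b <- bin[seq.int(1L + T, n)]
    joint <- tabulate((a - 1L) * n_bins + b, nbins = n_bins * n_bins)
    joint <- matrix(joint, n_bins, n_bins, byrow = TRUE) / (n - T)
    pi_ <- rowSums(joint)
    pj <- colSums(joint)
    nz <- which(joint > 0, arr.ind = TRUE)
    p <- joint[nz]
    sum(p * log2(p / (pi_[nz[, 1]] * pj[nz[, 2]])))
  }, numeric(1))
  structure(data.frame(lag = 0:t_max, ami = ami),
            class = c("ami_profile", "data.frame"))
}

#' @export
plot.ami_profile <- function(x, ...) {
  graphics::plot(x$lag, x$ami, type = "b", xlab = "lag (samples)",
                 ylab = "average mutual information (bits)", ...)
  invisible(x)
}

#' Embedding delay from the first minimum of the AMI profile
#'
#' Returns the smallest lag `T >= 1` that is a strict interior minimum of
#' the profile (`I(T-1) > I(T) < I(T+1)`). If no interior minimum exists
#' up to `t_max`, the conventional small delay 2 is returned with a
#' message.
#'
#' @param profile an `"ami_profile"` from [average_mutual_information()],
#'   or a plain numeric vector of AMI values at lags `0, 1, ...`.
#' @param fallback delay returned when the profile has no interior
#'   minimum.
#' @return Integer delay in samples.
#' @export
select_delay <- function(profile, fallback = 2L) {
  v <- if (inherits(profile, "data.frame")) profile$ami else as.numeric(profile)
  stopifnot(length(v) >= 3L)
  for (t in seq.int(1L, length(v) - 2L)) {
    # v[t + 1] is I(t): profiles start at lag 0
    if (v[t] > v[t + 1] && v[t + 1] < v[t + 2]) return(t)
  }
  message("no interior AMI minimum up to t_max; falling back to T = ",
          fallback)
  as.integer(fallback)
}

#' Time-delay embedding
#'
#' Builds the delay-coordinate trajectory matrix whose row `n` is
#' `[x(n), x(n+T), ..., x(n+(d-1)T)]`.
#'
#' @param series numeric vector (or [eeg_block()]).
#' @param T delay in samples (>= 1).
#' @param d embedding dimension (>= 2).
#' @return A numeric matrix with `length(series) - (d-1)*T` rows and `d`
#'   columns.
#' @examples
#' delay_embed(1:5, T = 1, d = 2)
#' @export
delay_embed <- function(series, T, d = 2) {
  x <- as.numeric(series)
  T <- as.integer(T); d <- as.integer(d)
  stopifnot(T >= 1, d >= 2)
  n_rows <- length(x) - (d - 1L) * T
  if (n_rows < 1L)
    stop(sprintf("series too short: need > %d samples for d = %d, T = %d",
                 (d - 1L) * T, d, T))
  out <- vapply(seq_len(d), function(j) x[seq.int((j - 1L) * T + 1L,
                                                  (j - 1L) * T + n_rows)],
                numeric(n_rows))
  if (n_rows == 1L) out <- matrix(out, nrow = 1L)
  out
}
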