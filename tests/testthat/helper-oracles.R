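# Independent reference implementations used to check the package's
# optimized code paths. These are deliberately literal and slow.

# Sample entropy straight from its defining count formulas: templates
# X_m(i) = [x(i), ..., x(i+m-1)], i = 1..N-m, pairs i != k within Euclidean
# (or Chebyshev) distance r; counts normalized by (N-m)(N-m-1) at length m
# and (N-m-1)(N-m-2) at length m+1.
sampen_bruteforce <- function(x, m = 2, r_factor = 0.25,
                              metric = "euclidean") {
  n <- length(x)
  r <- r_factor * sd(x)
  count_level <- function(mlen, imax) {
    cnt <- 0
    for (i in seq_len(imax)) {
      for (k in seq_len(imax)) {
        if (k == i) next
        d <- x[i:(i + mlen - 1)] - x[k:(k + mlen - 1)]
        dist <- if (metric == "euclidean") sqrt(sum(d^2)) else max(abs(d))
        if (dist <= r) cnt <- cnt + 1
      }
    }
    cnt
  }
  um <- count_level(m, n - m) / ((n - m) * (n - m - 1))
  um1 <- count_level(m + 1, n - m - 1) / ((n - m - 1) * (n - m - 2))
  if (um == 0 || um1 == 0) return(Inf)
  -log(um1 / um)
}

# Shannon entropy by direct counting (no tabulate()).
shannon_counts <- function(x, n_bins = 10) {
  rng <- range(x)
  width <- (rng[2] - rng[1]) / n_bins
  counts <- vapply(seq_len(n_bins), function(b) {
    lo <- rng[1] + (b - 1) * width
    hi <- rng[1] + b * width
    if (b == n_bins) sum(x >= lo & x <= hi) else sum(x >= lo & x < hi)
  }, numeric(1))
  p <- counts / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Analytic eigenfrequencies (Hz) of the linear stiffness matrix.
linear_eigenfreqs <- function(k1, k2) {
  K <- matrix(c(k1 + k2, -k2, -k2, k2), 2, 2)
  sqrt(sort(eigen(K, symmetric = TRUE)$values)) / (2 * pi)
}

# Short white-noise block at 125 Hz for feature tests.
noise_block <- function(n = 2000, seed = 1, fs = 125) {
  set.seed(seed)
  eeg_block(rnorm(n), fs = fs)
}

sine_block <- function(freq, duration = 40, fs = 125, phase = 0) {
  t <- seq.int(0, duration * fs - 1) / fs
  eeg_block(sin(2 * pi * freq * t + phase), fs = fs)
}
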