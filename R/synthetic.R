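# Per-block seed derivation: a documented counter scheme off the master
# seed, keeping every derived seed a valid 32-bit integer.
block_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647)
}

#' Spectral profile of a synthetic resting-EEG condition
#'
#' Describes one recording condition by its target fractional band powers
#' plus a broadband 1/f "floor" weight that controls how much of each
#' band's power is spread 1/f-style across the band (rather than flat).
#' The built-in profiles encode the qualitative resting-state spectra:
#' eyes-closed controls are alpha-dominant, eyes-closed AD blocks are
#' slightly theta-dominant (the classic EEG "slowing"), and eyes-open
#' blocks have a flat spectrum from upper delta through lower beta with
#' no band above 0.35.
#'
#' @param condition one of `"EC-CTL"`, `"EO-CTL"`, `"EC-AD"`, `"EO-AD"`,
#'   or `"custom"` (then `band_fractions` is required).
#' @param band_fractions length-7 non-negative vector summing to 1
#'   (order as [eeg_bands()]); overrides the built-in profile.
#' @param noise_floor 1/f spectral-shaping weight in `[0, 1]`.
#' @param fs sampling rate (Hz).
#' @param duration block duration (s).
#' @return An object of class `"surrogate_profile"`.
#' @examples
#' surrogate_profile("EC-CTL")
#' @export
surrogate_profile <- function(condition = c("EC-CTL", "EO-CTL", "EC-AD",
                                            "EO-AD", "custom"),
                              band_fractions = NULL, noise_floor = 0.3,
                              fs = 125, duration = 40) {
  condition <- match.arg(condition)
  defaults <- list(
    "EC-CTL" = c(0.03, 0.07, 0.15, 0.45, 0.15, 0.10, 0.05),
    "EO-CTL" = c(0.06, 0.20, 0.22, 0.22, 0.18, 0.08, 0.04),
    "EC-AD"  = c(0.04, 0.10, 0.32, 0.28, 0.12, 0.09, 0.05),
    "EO-AD"  = c(0.07, 0.22, 0.25, 0.20, 0.14, 0.08, 0.04))
  if (is.null(band_fractions)) {
    if (condition == "custom")
      stop("band_fractions required for a custom profile")
    band_fractions <- defaults[[condition]]
  }
  band_fractions <- as.numeric(band_fractions)
  stopifnot(length(band_fractions) == 7L, all(band_fractions >= 0),
            abs(sum(band_fractions) - 1) < 1e-6,
            noise_floor >= 0, noise_floor <= 1, fs > 0, duration > 0)
  structure(list(condition = condition,
                 band_fractions = stats::setNames(band_fractions,
                                                  eeg_bands()$name),
                 noise_floor = noise_floor, fs = fs, duration = duration),
            class = "surrogate_profile")
}

#' @export
print.surrogate_profile <- function(x, ...) {
  cat(sprintf("<surrogate_profile> %s, %g s @ %g Hz, 1/f weight %.2f\n",
              x$condition, x$duration, x$fs, x$noise_floor))
  print(round(x$band_fractions, 3))
  invisible(x)
}

# One surrogate realisation: Gaussian random-phase spectrum shaped band by
# band so each band's power equals its profile fraction exactly, with a
# 1/f-weighted component inside each band; zero outside 1-60 Hz (the
# hardware band limit), unit-SD in time domain.
surrogate_block_once <- function(profile) {
  n <- round(profile$fs * profile$duration)
  freq <- seq.int(0, n - 1) * profile$fs / n
  half <- 2:(ceiling(n / 2))  # positive frequencies, DC excluded
  f <- freq[half]
  bands <- eeg_bands()
  amp2 <- numeric(length(f))
  for (i in seq_len(nrow(bands))) {
    hi_closed <- bands$hi[i] == max(bands$hi)
    sel <- f >= bands$lo[i] &
      (if (hi_closed) f <= bands$hi[i] else f < bands$hi[i])
    if (!any(sel)) next
    flat <- rep(1, sum(sel)) / sum(sel)
    pink <- (1 / f[sel]) / sum(1 / f[sel])
    shape <- (1 - profile$noise_floor) * flat + profile$noise_floor * pink
    amp2[sel] <- profile$band_fractions[i] * shape
  }
  z <- complex(real = stats::rnorm(length(f)),
               imaginary = stats::rnorm(length(f))) / sqrt(2)
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  spec[half] <- sqrt(amp2) * z
  spec[n - half + 2] <- Conj(spec[half])
  x <- Re(stats::fft(spec, inverse = TRUE))
  x / stats::sd(x)
}

#' Generate model-independent surrogate EEG blocks
#'
#' Each block is band-limited (1--60 Hz) Gaussian noise whose spectrum is
#' shaped so the realised fractional band powers match the profile, with a
#' 1/f component within each band giving the broadband character of
#' resting EEG. Blocks are normalised to unit SD and are fully
#' seed-deterministic (block `i` uses a seed derived from `seed` by a
#' fixed counter scheme).
#'
#' @param profile a [surrogate_profile()].
#' @param n_blocks number of blocks.
#' @param seed master seed.
#' @return List of [eeg_block()]s, each carrying its profile and seed in
#'   `meta`.
#' @examples
#' b <- generate_surrogate_blocks(surrogate_profile("EC-CTL"), 1, seed = 1)[[1]]
#' which.max(band_powers(b))  # alpha
#' @export
generate_surrogate_blocks <- function(profile, n_blocks, seed = 1) {
  stopifnot(inherits(profile, "surrogate_profile"), n_blocks >= 0)
  cond <- strsplit(profile$condition, "-")[[1]]
  lapply(seq_len(n_blocks), function(i) {
    set.seed(block_seed(seed, i))
    eeg_block(surrogate_block_once(profile), fs = profile$fs,
              condition = cond[1],
              group = if (length(cond) > 1) cond[2] else NA_character_,
              meta = list(profile = profile$condition,
                          band_fractions = as.list(profile$band_fractions),
                          noise_floor = profile$noise_floor,
                          seed = block_seed(seed, i)))
  })
}

#' Generate blocks from the oscillator model with stored ground truth
#'
#' Runs [simulate_oscillator()] `n_blocks` times with per-block derived
#' seeds; each block's `meta` records the generating parameters, so the
#' set can serve as ground truth for fit-recovery experiments.
#'
#' @param params an [osc_params()] set (must pass [check_bounds()]).
#' @param n_blocks number of blocks.
#' @param seed master seed.
#' @param ... passed to [simulate_oscillator()].
#' @return List of [eeg_block()]s.
#' @export
generate_model_blocks <- function(params, n_blocks, seed = 1, ...) {
  chk <- check_bounds(params)
  if (!chk$feasible)
    stop("infeasible parameters: ", paste(chk$violations, collapse = "; "))
  lapply(seq_len(n_blocks), function(i) {
    simulate_oscillator(params, seed = block_seed(seed, i), ...)
  })
}

#' Inject high-amplitude transient artifacts into a block
#'
#' Adds `rate` smooth (raised-cosine) bumps of the given amplitude (in
#' multiples of the clean block's SD) and width at uniformly drawn,
#' non-overlapping positions, emulating eye/muscle artifacts at a frontal
#' electrode. The returned ground-truth mask marks the contaminated
#' samples.
#'
#' @param block an [eeg_block()].
#' @param rate number of artifact events.
#' @param amplitude bump peak in multiples of the block SD (> 4.5 so the
#'   detection rule can see it).
#' @param width bump width in samples.
#' @param seed RNG seed.
#' @return List with `block` (contaminated) and `mask` (logical truth).
#' @examples
#' b <- generate_surrogate_blocks(surrogate_profile("EC-CTL"), 1, 1)[[1]]
#' dirty <- inject_artifacts(b, seed = 2)
#' sum(dirty$mask)
#' @export
inject_artifacts <- function(block, rate = 3, amplitude = 8, width = 12,
                             seed = 1) {
  stopifnot(rate >= 0, amplitude > 4.5, width >= 1)
  x <- as.numeric(block)
  n <- length(x)
  if (rate == 0)
    return(list(block = block, mask = rep(FALSE, n)))
  set.seed(seed)
  s <- stats::sd(x)
  bump <- amplitude * s * 0.5 * (1 - cos(2 * pi * seq_len(width) / (width + 1)))
  mask <- rep(FALSE, n)
  placed <- 0L
  for (attempt in seq_len(100L * rate)) {
    if (placed >= rate) break
    start <- sample.int(n - width + 1L, 1L)
    span <- start:(start + width - 1L)
    if (any(mask[span])) next  # overlap: redraw
    x[span] <- x[span] + sample(c(-1, 1), 1) * bump
    mask[span] <- TRUE
    placed <- placed + 1L
  }
  if (placed < rate)
    warning("placed only ", placed, " of ", rate, " artifacts")
  list(block = block_like(x, block), mask = mask)
}
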