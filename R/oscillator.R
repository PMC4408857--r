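#' Oscillator parameter set
#'
#' The seven physical parameters of the coupled stochastic Duffing-van der
#' Pol pair: linear stiffnesses `k1`, `k2` (1/s^2), cubic (Duffing)
#' stiffnesses `b1`, `b2`, van der Pol damping coefficients `eps1`, `eps2`,
#' and white-noise intensity `mu`. All stiffness/damping coefficients must
#' be strictly positive and `mu` non-negative; the tighter box used by the
#' fitter is enforced separately by [check_bounds()].
#'
#' @param k1,k2 linear stiffness, > 0.
#' @param b1,b2 cubic stiffness, > 0.
#' @param eps1,eps2 van der Pol damping, > 0.
#' @param mu noise intensity, >= 0.
#' @return A named numeric vector of class `"osc_params"` in the order
#'   `k1, k2, b1, b2, eps1, eps2, mu`.
#' @examples
#' osc_params(7286.5, 4523.5, 232.05, 10.78, 33.60, 0.97, 2.34)
#' @export
osc_params <- function(k1, k2, b1, b2, eps1, eps2, mu) {
  p <- stats::setNames(as.numeric(c(k1, k2, b1, b2, eps1, eps2, mu)),
                       c("k1", "k2", "b1", "b2", "eps1", "eps2", "mu"))
  stopifnot(length(p) == 7L)
  if (!all(is.finite(p)))
    stop("all oscillator parameters must be finite")
  if (any(p[1:6] <= 0) || p[["mu"]] < 0)
    stop("require k1,k2,b1,b2,eps1,eps2 > 0 and mu >= 0")
  structure(p, class = "osc_params")
}

#' @export
print.osc_params <- function(x, ...) {
  cat("<osc_params>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

as_osc_params <- function(p) {
  if (inherits(p, "osc_params")) return(p)
  p <- unlist(p)
  if (!is.null(names(p)) && all(c("k1", "k2", "b1", "b2", "eps1", "eps2",
                                  "mu") %in% names(p)))
    p <- p[c("k1", "k2", "b1", "b2", "eps1", "eps2", "mu")]
  stopifnot(length(p) == 7L)
  osc_params(p[[1]], p[[2]], p[[3]], p[[4]], p[[5]], p[[6]], p[[7]])
}

#' Drift field of the coupled oscillator system
#'
#' Deterministic part of the state equations. For state
#' `(x1, v1, x2, v2)` the accelerations are
#' \deqn{\dot v_1 = -(k_1+k_2)x_1 + k_2 x_2 - b_1 x_1^3 - b_2 (x_1-x_2)^3
#'   + \epsilon_1 v_1 (1 - x_1^2)}
#' \deqn{\dot v_2 = k_2 x_1 - k_2 x_2 + b_2 (x_1-x_2)^3
#'   + \epsilon_2 v_2 (1 - x_2^2)}
#' The stochastic forcing `mu dW` is not part of the drift; the integrator
#' adds it to `v2` only.
#'
#' @param state numeric length-4 vector `(x1, v1, x2, v2)`.
#' @param params an [osc_params()] set.
#' @return Numeric length-4 derivative `(dx1, dv1, dx2, dv2)`.
#' @examples
#' p <- osc_params(2, 1, 1, 1, 1, 1, 0)
#' osc_drift(c(1, 0, 0, 0), p)  # dv1 = -5, dv2 = 2
#' @export
osc_drift <- function(state, params) {
  if (!all(is.finite(state)))
    stop("non-finite oscillator state")
  params <- as_osc_params(params)
  x1 <- state[[1]]; v1 <- state[[2]]; x2 <- state[[3]]; v2 <- state[[4]]
  d3 <- (x1 - x2)^3
  dv1 <- -(params[["k1"]] + params[["k2"]]) * x1 + params[["k2"]] * x2 -
    params[["b1"]] * x1^3 - params[["b2"]] * d3 +
    params[["eps1"]] * v1 * (1 - x1^2)
  dv2 <- params[["k2"]] * x1 - params[["k2"]] * x2 + params[["b2"]] * d3 +
    params[["eps2"]] * v2 * (1 - x2^2)
  c(v1, dv1, v2, dv2)
}

#' In-phase eigenmode initial state
#'
#' Starting state on the lower (in-phase) eigenvector of the linear
#' stiffness matrix `[[k1 + k2, -k2], [-k2, k2]]`, scaled so the larger
#' position component equals `amplitude`, with zero velocities. The
#' coupled system is bistable over part of its parameter range: a small
#' or zero start can fall into the basin of an anti-phase high-frequency
#' limit cycle, while the in-phase start selects the slower
#' resting-EEG-like regime (alpha-dominant at the eyes-closed control
#' parameters). A self-excited oscillator is never observed at rest, so
#' this is the simulator's default start.
#'
#' @param params an [osc_params()] set.
#' @param amplitude position amplitude of the larger component.
#' @return Numeric length-4 state `(x1, 0, x2, 0)`.
#' @examples
#' inphase_state(reference_params("EC-CTL"))
#' @export
inphase_state <- function(params, amplitude = 1.5) {
  p <- unclass(as_osc_params(params))
  K <- matrix(c(p[["k1"]] + p[["k2"]], -p[["k2"]],
                -p[["k2"]], p[["k2"]]), 2, 2)
  e <- eigen(K, symmetric = TRUE)
  v <- e$vectors[, which.min(e$values)]
  v <- v * sign(v[which.max(abs(v))])  # orient positive (in-phase)
  v <- v / max(abs(v)) * amplitude
  c(v[1], 0, v[2], 0)
}

#' Simulate the stochastic oscillator pair by Euler-Maruyama
#'
#' Integrates the coupled Duffing-van der Pol system with an explicit
#' Euler-Maruyama scheme at internal step `h = 1/(fs * substeps)` and
#' returns one state component (by default the velocity of the second
#' oscillator, the EEG-mimicking output) sampled at `fs`. Per internal
#' step the velocity `v2` receives the increment `mu * sqrt(h) * z` with
#' `z` a standard normal draw. A burn-in period is simulated before the
#' recorded window and discarded, removing dependence on the (arbitrary)
#' zero initial state.
#'
#' Identical `(params, config, seed)` give bit-identical output.
#'
#' @param params an [osc_params()] set (any positive values; the fitter's
#'   box constraints are checked by [check_bounds()], not here).
#' @param fs output sampling rate (Hz).
#' @param duration recorded duration (s); the returned block has
#'   `fs * duration` samples.
#' @param substeps internal integration steps per output sample (>= 1).
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @param burn_in transient discarded before recording (s).
#' @param initial_state state `(x1, v1, x2, v2)` at t = 0; the default
#'   `NULL` uses [inphase_state()] (see there for why), `c(0, 0, 0, 0)`
#'   gives the rest start.
#' @param output_channel which state component to return: `"v2"`
#'   (default), `"x1"`, `"v1"` or `"x2"`.
#' @param noise optional vector of pre-generated standard-normal
#'   increments, one per internal step (burn-in included); used by the
#'   convergence diagnostic to share a Wiener path across refinements.
#' @return An [eeg_block()] with the simulation settings in its `meta`.
#' @examples
#' p <- reference_params("EC-CTL")
#' b <- simulate_oscillator(p, duration = 4, seed = 1)
#' b
#' @export
simulate_oscillator <- function(params, fs = 125, duration = 40,
                                substeps = 10, seed = NULL, burn_in = 2,
                                initial_state = NULL,
                                output_channel = c("v2", "x1", "v1", "x2"),
                                noise = NULL) {
  params <- as_osc_params(params)
  output_channel <- match.arg(output_channel)
  if (is.null(initial_state)) initial_state <- inphase_state(params)
  stopifnot(fs > 0, duration > 0, substeps >= 1, burn_in >= 0,
            length(initial_state) == 4L, all(is.finite(initial_state)))
  substeps <- as.integer(substeps)
  h <- 1 / (fs * substeps)
  n_out <- round(fs * (duration + burn_in))
  n_steps <- n_out * substeps
  if (!is.null(noise)) {
    stopifnot(length(noise) == n_steps)
  } else {
    noise <- numeric(0)
    if (!is.null(seed)) {
      # seed the draw but leave the caller's RNG stream untouched
      if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
      }
      set.seed(seed)
    }
  }
  res <- .sim_dvp_cpp(unclass(params), h, n_steps, substeps,
                      as.numeric(initial_state), as.numeric(noise))
  if (isTRUE(res$blowup)) {
    stop(structure(class = c("osc_blowup", "error", "condition"),
                   list(message = sprintf(
                     "numerical blow-up at internal step %d (k1=%g, k2=%g, b1=%g, b2=%g, eps1=%g, eps2=%g, mu=%g)",
                     res$step, params[[1]], params[[2]], params[[3]],
                     params[[4]], params[[5]], params[[6]], params[[7]]),
                     call = NULL, step = res$step, params = params)))
  }
  col <- match(output_channel, c("x1", "v1", "x2", "v2"))
  out <- res$states[, col]
  keep <- seq.int(round(fs * burn_in) + 1L, n_out)
  eeg_block(out[keep], fs = fs,
            meta = list(params = as.list(unclass(params)), seed = seed,
                        substeps = substeps, burn_in = burn_in,
                        duration = duration,
                        output_channel = output_channel))
}

#' Step-size convergence diagnostic for the Euler-Maruyama scheme
#'
#' Integrates a short horizon on a shared Wiener path at several internal
#' step refinements and reports the endpoint state error against a
#' reference computed at `substeps * 8`. For the deterministic case
#' (`mu = 0`) the error should fall roughly linearly in the step size
#' (order-1 explicit Euler); in the stochastic case the strong error on a
#' common path should shrink monotonically as the step is refined.
#'
#' @param params an [osc_params()] set.
#' @param fs output sampling rate (Hz).
#' @param substeps base refinement level (the coarsest tested).
#' @param horizon integration horizon (s), at most 2.
#' @param seed RNG seed for the shared Wiener path.
#' @param initial_state starting state.
#' @return A data.frame with columns `substeps`, `h` and `err` (Euclidean
#'   endpoint error vs. the reference), rows ordered coarse to fine
#'   (`substeps`, `2*substeps`, `4*substeps`).
#' @export
em_convergence <- function(params, fs = 125, substeps = 1, horizon = 1,
                           seed = 1, initial_state = c(1, 0, 0, 0)) {
  stopifnot(horizon > 0, horizon <= 2)
  params <- as_osc_params(params)
  levels <- substeps * c(1L, 2L, 4L)
  ref_level <- substeps * 8L
  n_out <- round(fs * horizon)
  # finest-grid standard-normal increments; aggregate to each coarser grid so
  # every level sees the same Wiener path
  set.seed(seed)
  z_fine <- stats::rnorm(n_out * ref_level)
  h_fine <- 1 / (fs * ref_level)
  dw_fine <- sqrt(h_fine) * z_fine
  endpoint <- function(level) {
    agg <- ref_level / level
    h <- 1 / (fs * level)
    dw <- colSums(matrix(dw_fine, nrow = agg))
    z <- dw / sqrt(h)
    res <- .sim_dvp_cpp(unclass(params), h, n_out * level, level,
                        as.numeric(initial_state), z)
    if (isTRUE(res$blowup)) stop("blow-up during convergence check")
    res$final
  }
  ref <- endpoint(ref_level)
  err <- vapply(levels, function(l) sqrt(sum((endpoint(l) - ref)^2)),
                numeric(1))
  data.frame(substeps = levels, h = 1 / (fs * levels), err = err)
}

#' Published group-mean oscillator parameters
#'
#' Mean fitted parameter values reported for the four resting-state groups
#' (eyes-closed/eyes-open in control and Alzheimer's cohorts), usable as
#' simulation inputs for reproducing the model-output feature values.
#'
#' @param group one of `"EC-CTL"`, `"EO-CTL"`, `"EC-AD"`, `"EO-AD"`.
#' @return An [osc_params()] set.
#' @examples
#' reference_params("EO-CTL")
#' @export
reference_params <- function(group = c("EC-CTL", "EO-CTL", "EC-AD", "EO-AD")) {
  group <- match.arg(group)
  switch(group,
    "EC-CTL" = osc_params(7286.5, 4523.5, 232.05, 10.78, 33.60, 0.97, 2.34),
    "EO-CTL" = osc_params(2427.2, 499.92, 95.61, 103.36, 48.89, 28.75, 1.82),
    "EC-AD"  = osc_params(1742.1, 1270.8, 771.99, 1.91, 63.7, 20.7, 1.78),
    "EO-AD"  = osc_params(3139.9, 650.32, 101.1, 81.3, 56.3, 19.12, 1.74))
}
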