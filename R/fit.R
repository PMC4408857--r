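#' Feasibility of an oscillator parameter set
#'
#' The fitter's box constraints: `0 < k_i <= 1e4`,
#' `0 < b_i <= k_i / 2`, `0 < eps_i <= k_i / 3` (keeping the cubic and
#' self-excitation terms weak relative to the linear stiffness, away from
#' the chaotic regime) and `0 <= mu <= 2` (so the response is not
#' noise-dominated).
#'
#' @param params an [osc_params()] set (or coercible).
#' @return A list with `feasible` (logical) and `violations` (character
#'   vector naming each violated constraint, empty when feasible).
#' @examples
#' check_bounds(reference_params("EO-CTL"))$feasible  # TRUE
#' check_bounds(reference_params("EC-CTL"))           # mu = 2.34 > 2
#' @export
check_bounds <- function(params) {
  p <- unclass(as_osc_params(params))
  v <- character(0)
  for (i in 1:2) {
    k <- p[[paste0("k", i)]]; b <- p[[paste0("b", i)]]
    e <- p[[paste0("eps", i)]]
    if (!(k > 0 && k <= 1e4))
      v <- c(v, sprintf("k%d = %g outside (0, 1e4]", i, k))
    if (!(b > 0 && b <= k / 2))
      v <- c(v, sprintf("b%d = %g outside (0, k%d/2 = %g]", i, b, i, k / 2))
    if (!(e > 0 && e <= k / 3))
      v <- c(v, sprintf("eps%d = %g outside (0, k%d/3 = %g]", i, e, i, k / 3))
  }
  if (!(p[["mu"]] >= 0 && p[["mu"]] <= 2))
    v <- c(v, sprintf("mu = %g outside [0, 2]", p[["mu"]]))
  list(feasible = length(v) == 0L, violations = v)
}

#' Objective: feature mismatch between model output and a target block
#'
#' Simulates `n_realizations` independent outputs at the given parameters,
#' extracts each [feature_vector()] after unit-SD normalisation, averages
#' the features, and returns
#' \deqn{J = \sum_{j=1}^{7} (P_{Ej} - P_{Oj})^2 + w_1 |S_E - S_O|
#'   + w_2 |SP_E - SP_O|}
#' where `P` are fractional band powers, `S` Shannon entropies and `SP`
#' sample entropies of the target (`E`) and model output (`O`). Parameter
#' sets outside the [check_bounds()] box, and simulations that blow up,
#' return `Inf`.
#'
#' @param params an [osc_params()] set.
#' @param target a `"feature_vector"` (from [feature_vector()]) the model
#'   output should match.
#' @param weights length-2 numeric `(w1, w2)`: weights on the Shannon and
#'   sample-entropy absolute errors. The default 0.35/0.35 balances the
#'   entropy terms against the band-power term.
#' @param seeds integer vector of simulation seeds, one per realization
#'   (recycled); `NULL` leaves the RNG stream untouched (fresh noise).
#' @param n_realizations independent simulations averaged per evaluation.
#' @param bands_used indices of the bands entering the power-error sum
#'   (default all 7; `2:6` restricts to the reliably recorded upper-delta
#'   through upper-beta range).
#' @param sim_args list of extra arguments for [simulate_oscillator()]
#'   (e.g. `fs`, `duration`, `substeps`).
#' @param details if `TRUE`, return a list with `J`, the per-term errors
#'   and the averaged model features instead of the bare value.
#' @return The objective value (or a detail list).
#' @export
osc_objective <- function(params, target, weights = c(0.35, 0.35),
                          seeds = NULL, n_realizations = 5,
                          bands_used = 1:7, sim_args = list(),
                          details = FALSE) {
  target <- as_feature_vector(target)
  stopifnot(length(weights) == 2L, all(weights >= 0), n_realizations >= 1)
  chk <- check_bounds(params)
  if (!chk$feasible) {
    if (details) return(list(J = Inf, infeasible = chk$violations))
    return(Inf)
  }
  if (!is.null(seeds)) seeds <- rep_len(seeds, n_realizations)
  fvs <- vector("list", n_realizations)
  for (i in seq_len(n_realizations)) {
    blk <- tryCatch(
      do.call(simulate_oscillator,
              c(list(params = params, seed = seeds[i]), sim_args)),
      osc_blowup = function(e) NULL)
    if (is.null(blk)) {
      if (details) return(list(J = Inf, blowup = TRUE))
      return(Inf)
    }
    fvs[[i]] <- feature_vector(blk)
  }
  avg <- average_features(fvs)
  out <- objective_from_features(target, avg, weights, bands_used)
  if (details) c(out, list(model_features = avg)) else out$J
}

# The mismatch functional on two feature vectors: band-power sum of squares
# plus weighted absolute entropy errors.
objective_from_features <- function(target, model, weights = c(0.35, 0.35),
                                    bands_used = 1:7) {
  band_err <- (target$band_powers[bands_used] -
                 model$band_powers[bands_used])^2
  s_err <- abs(target$shannon - model$shannon)
  sp_err <- abs(target$sampen - model$sampen)
  list(J = sum(band_err) + weights[1] * s_err + weights[2] * sp_err,
       band_sq_err = band_err, shannon_abs_err = s_err,
       sampen_abs_err = sp_err)
}

# Internal coordinates z in R^7 <-> feasible parameter box.  k via scaled
# logistic into (0, 1e4); b and eps as logistic fractions of their k-linked
# caps, so the box constraints hold for every z; mu logistic into [0, 2].
z_to_params <- function(z) {
  sig <- stats::plogis(z)
  k1 <- 1e4 * sig[1]; k2 <- 1e4 * sig[2]
  osc_params(k1, k2,
             b1 = sig[3] * k1 / 2, b2 = sig[4] * k2 / 2,
             eps1 = sig[5] * k1 / 3, eps2 = sig[6] * k2 / 3,
             mu = 2 * sig[7])
}

params_to_z <- function(params) {
  p <- unclass(as_osc_params(params))
  clamp <- function(u) pmin(pmax(u, 1e-9), 1 - 1e-9)
  stats::qlogis(clamp(c(p[["k1"]] / 1e4, p[["k2"]] / 1e4,
                        2 * p[["b1"]] / p[["k1"]], 2 * p[["b2"]] / p[["k2"]],
                        3 * p[["eps1"]] / p[["k1"]],
                        3 * p[["eps2"]] / p[["k2"]],
                        p[["mu"]] / 2)))
}

#' Fit the oscillator model to a target block's features
#'
#' Multi-start bounded minimisation of [osc_objective()]: `n_starts`
#' parameter sets are drawn uniformly inside the feasible box, a
#' derivative-free Nelder-Mead local search (run in a transformed
#' coordinate system that enforces the box exactly) refines each, and the
#' best feasible result is returned. With `noise_mode = "frozen"` each
#' evaluation reuses a fixed set of simulation seeds (common random
#' numbers), giving a deterministic, much smoother objective;
#' `"fresh"` draws new noise every evaluation, mirroring a literal
#' per-iteration re-randomisation. The whole search is reproducible from
#' `seed`.
#'
#' @param target a `"feature_vector"`, or an [eeg_block()] (features are
#'   extracted first).
#' @param n_starts number of random feasible starting points.
#' @param weights entropy-error weights `(w1, w2)`, see [osc_objective()].
#' @param n_realizations simulations averaged per objective evaluation.
#' @param seed master RNG seed for starts and simulation seeds.
#' @param noise_mode `"frozen"` (common random numbers per fit) or
#'   `"fresh"`.
#' @param bands_used band indices entering the objective (see
#'   [osc_objective()]).
#' @param sim_args extra [simulate_oscillator()] arguments.
#' @param maxeval local-search evaluation cap per start.
#' @param reltol local-search relative convergence tolerance on J.
#' @return An object of class `"osc_fit"`: list with `params`
#'   ([osc_params()]), `J`, `term_errors` (7 band squared errors and the 2
#'   absolute entropy errors at the optimum), `model_features`, `target`,
#'   `starts` (per-start summary data.frame), plus the fit configuration.
#' @examples
#' \donttest{
#' tgt <- feature_vector(simulate_oscillator(reference_params("EO-CTL"),
#'                                           duration = 10, seed = 7))
#' fit <- fit_oscillator(tgt, n_starts = 2, n_realizations = 2,
#'                       sim_args = list(duration = 10), maxeval = 40,
#'                       seed = 1)
#' coef(fit)
#' }
#' @export
fit_oscillator <- function(target, n_starts = 20, weights = c(0.35, 0.35),
                           n_realizations = 5, seed = 1,
                           noise_mode = c("frozen", "fresh"),
                           bands_used = 1:7, sim_args = list(),
                           maxeval = 500, reltol = 1e-4) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(n_starts >= 1)
  if (inherits(target, "eeg_block") ||
      (is.numeric(target) && !is.list(target)))
    target <- feature_vector(target)
  target <- as_feature_vector(target)
  set.seed(seed)
  z_starts <- matrix(stats::qlogis(stats::runif(7 * n_starts, 0.001, 0.999)),
                     ncol = 7)
  start_seeds <- sample.int(.Machine$integer.max - 1L, n_starts)
  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    eval_seeds <- if (noise_mode == "frozen") {
      set.seed(start_seeds[s])
      sample.int(.Machine$integer.max - 1L, n_realizations)
    } else NULL
    n_eval <- 0L
    fun <- function(z) {
      n_eval <<- n_eval + 1L
      J <- osc_objective(z_to_params(z), target, weights = weights,
                         seeds = eval_seeds, n_realizations = n_realizations,
                         bands_used = bands_used, sim_args = sim_args)
      # blow-ups penalized with a large finite value so the simplex can
      # retreat from them
      if (!is.finite(J)) 1e6 else J
    }
    if (noise_mode == "fresh") set.seed(start_seeds[s])
    # parts of the box blow up under the explicit scheme (very stiff van der
    # Pol damping); redraw such starts so the local search begins on a
    # finite objective
    z0 <- z_starts[s, ]
    if (fun(z0) >= 1e6) {
      # draw all candidates first: objective evaluations reseed the RNG
      set.seed(start_seeds[s] + 7919L)
      cand <- matrix(stats::qlogis(stats::runif(7 * 50, 0.001, 0.999)),
                     ncol = 7)
      for (try in 1:50) {
        z0 <- cand[try, ]
        if (fun(z0) < 1e6) break
      }
    }
    opt <- stats::optim(z0, fun, method = "Nelder-Mead",
                        control = list(maxit = maxeval, reltol = reltol))
    starts[[s]] <- list(z = opt$par, J = opt$value, n_eval = n_eval,
                        seed = start_seeds[s], eval_seeds = eval_seeds,
                        convergence = opt$convergence)
  }
  js <- vapply(starts, `[[`, numeric(1), "J")
  if (all(!is.finite(js) | js >= 1e6))
    stop("all starts infeasible or blown up; no feasible fit found")
  best <- starts[[which.min(js)]]
  best_params <- z_to_params(best$z)
  det <- osc_objective(best_params, target, weights = weights,
                       seeds = best$eval_seeds,
                       n_realizations = n_realizations,
                       bands_used = bands_used, sim_args = sim_args,
                       details = TRUE)
  structure(list(
    params = best_params,
    J = best$J,
    term_errors = c(det$band_sq_err,
                    shannon = det$shannon_abs_err,
                    sampen = det$sampen_abs_err),
    model_features = det$model_features,
    target = target,
    weights = weights,
    n_starts = n_starts,
    n_realizations = n_realizations,
    noise_mode = noise_mode,
    seed = seed,
    bands_used = bands_used,
    sim_args = sim_args,
    starts = data.frame(
      start = seq_len(n_starts),
      J = js,
      n_eval = vapply(starts, `[[`, integer(1), "n_eval"),
      seed = vapply(starts, `[[`, numeric(1), "seed")),
    call = match.call()),
    class = "osc_fit")
}

#' @export
print.osc_fit <- function(x, ...) {
  cat("Stochastic Duffing-van der Pol fit\n")
  cat(sprintf("  J = %.5f after %d start(s) (%s noise, %d realization(s)/eval)\n",
              x$J, x$n_starts, x$noise_mode, x$n_realizations))
  cat("  parameters:\n")
  print(round(unclass(x$params), 4))
  invisible(x)
}

#' @export
coef.osc_fit <- function(object, ...) {
  stats::setNames(as.numeric(object$params), names(object$params))
}

#' @export
summary.osc_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.osc_fit")
}

#' @export
print.summary.osc_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\n  feature match (target vs model output):\n")
  tab <- rbind(target = c(f$target$band_powers, shannon = f$target$shannon,
                          sampen = f$target$sampen),
               model = c(f$model_features$band_powers,
                         shannon = f$model_features$shannon,
                         sampen = f$model_features$sampen))
  print(round(tab, 4))
  cat("\n  per-start objective values:\n")
  print(summary(f$starts$J))
  invisible(x)
}

#' @export
residuals.osc_fit <- function(object, ...) object$term_errors

#' Simulate new blocks from a fitted oscillator model
#'
#' @param object an `"osc_fit"`.
#' @param nsim number of blocks.
#' @param seed integer seed; each block gets a seed derived from it.
#' @param ... passed to [simulate_oscillator()] (e.g. `duration`).
#' @return A list of [eeg_block()]s.
#' @export
simulate.osc_fit <- function(object, nsim = 1, seed = 1, ...) {
  args <- modifyList(object$sim_args, list(...))
  lapply(seq_len(nsim), function(i) {
    do.call(simulate_oscillator,
            c(list(params = object$params, seed = block_seed(seed, i)), args))
  })
}

#' @export
plot.osc_fit <- function(x, ...) {
  bp <- rbind(target = x$target$band_powers,
              model = x$model_features$band_powers)
  graphics::barplot(bp, beside = TRUE, las = 2,
                    legend.text = c("target", "model"),
                    ylab = "fraction of 1-60 Hz power",
                    main = sprintf("feature match, J = %.4f", x$J), ...)
  invisible(x)
}
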