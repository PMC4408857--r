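#' Per-parameter comparison of two groups of fitted parameters
#'
#' For each of the seven oscillator parameters: a two-sided unpaired
#' pooled-variance t-test (`welch = TRUE` switches to Welch), a two-sided
#' Wilcoxon rank-sum test (exact enumeration when both groups have at
#' most 10 observations and no ties; normal approximation with tie and
#' continuity correction otherwise), and Bonferroni-adjusted versions of
#' both (raw p times the number of parameters, capped at 1).
#'
#' @param a,b numeric matrices or data.frames, one row per fitted block,
#'   columns the 7 parameters (`k1, k2, b1, b2, eps1, eps2, mu`); at least
#'   2 rows each.
#' @param labels length-2 character, names of the groups.
#' @param welch use Welch's t instead of the pooled-variance t.
#' @return An object of class `"group_comparison"`: a data.frame with one
#'   row per parameter and columns `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `p_t`, `p_wilcox`, `p_t_bonf`, `p_wilcox_bonf`.
#' @examples
#' a <- matrix(rnorm(70, 5), 10, 7,
#'             dimnames = list(NULL, names(reference_params("EC-CTL"))))
#' b <- matrix(rnorm(70, 6), 10, 7, dimnames = dimnames(a))
#' compare_groups(a, b, labels = c("EC", "EO"))
#' @export
compare_groups <- function(a, b, labels = c("A", "B"), welch = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == ncol(b), nrow(a) >= 2, nrow(b) >= 2)
  params <- colnames(a)
  if (is.null(params)) params <- paste0("p", seq_len(ncol(a)))
  n_tests <- ncol(a)
  rows <- lapply(seq_len(ncol(a)), function(j) {
    xa <- a[, j]; xb <- b[, j]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0 &&
        mean(xa) == mean(xb)) {
      warning("zero variance and equal means for ", params[j],
              ": p = 1 reported")
      pt <- pw <- 1
    } else {
      pt <- tryCatch(
        stats::t.test(xa, xb, var.equal = !welch)$p.value,
        error = function(e) 1)
      pw <- wilcoxon_ranksum(xa, xb)
    }
    data.frame(parameter = params[j],
               mean_a = mean(xa), sd_a = stats::sd(xa),
               mean_b = mean(xb), sd_b = stats::sd(xb),
               p_t = pt, p_wilcox = pw)
  })
  out <- do.call(rbind, rows)
  out$p_t_bonf <- pmin(1, out$p_t * n_tests)
  out$p_wilcox_bonf <- pmin(1, out$p_wilcox * n_tests)
  structure(out, labels = labels, n_a = nrow(a), n_b = nrow(b),
            class = c("group_comparison", "data.frame"))
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  lab <- attr(x, "labels")
  cat(sprintf("Group comparison: %s (n = %d) vs %s (n = %d)\n",
              lab[1], attr(x, "n_a"), lab[2], attr(x, "n_b")))
  df <- data.frame(
    parameter = x$parameter,
    A = sprintf("%.4g ± %.3g", x$mean_a, x$sd_a),
    B = sprintf("%.4g ± %.3g", x$mean_b, x$sd_b),
    t = signif(x$p_t, 2),
    wilcoxon = signif(x$p_wilcox, 2),
    t_bonf = signif(x$p_t_bonf, 2),
    wilcoxon_bonf = signif(x$p_wilcox_bonf, 2))
  names(df)[2:3] <- lab
  print(df, row.names = FALSE)
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' `method = "exact"` enumerates the rank-sum null distribution (valid
#' without ties); `"normal"` uses the normal approximation with tie
#' correction and continuity correction; `"auto"` (default) picks exact
#' when both groups have at most 10 untied observations, mirroring the
#' small-sample regime of the study's group sizes.
#'
#' @param x,y numeric samples.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_ranksum(1:5, 6:10, method = "exact")  # 2/252
#' @export
wilcoxon_ranksum <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  ties <- any(duplicated(c(x, y)))
  exact <- switch(method,
                  auto = length(x) <= 10 && length(y) <= 10 && !ties,
                  exact = TRUE,
                  normal = FALSE)
  if (exact && ties)
    stop("exact enumeration is not defined with ties")
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Pooled-variance t-test from group summaries
#'
#' Two-sided unpaired t-test computed from `(n, mean, sd)` summaries
#' alone; equals [stats::t.test()] with `var.equal = TRUE` on the raw
#' data.
#'
#' @param n_a,mean_a,sd_a,n_b,mean_b,sd_b group summaries.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
t_test_summary <- function(n_a, mean_a, sd_a, n_b, mean_b, sd_b) {
  stopifnot(n_a >= 2, n_b >= 2)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  t <- (mean_a - mean_b) / se
  list(statistic = t, df = df, p.value = 2 * stats::pt(-abs(t), df))
}

#' Minimum detectable mean difference (two-sample power analysis)
#'
#' Normal-approximation minimum difference between two group means
#' detectable at significance `alpha` (two-sided) with the requested
#' power:
#' \deqn{\Delta = (z_{1-\alpha/2} + z_{power}) \, s_{pooled}
#'   \sqrt{1/n_a + 1/n_b}}
#'
#' @param n_a,sd_a,n_b,sd_b group sizes and standard deviations (sds > 0,
#'   ns >= 2). `sd_a`/`sd_b` may be vectors (one element per parameter).
#' @param power target power level(s) in (0, 1).
#' @param alpha two-sided significance level.
#' @return A data.frame with one row per element of `sd_a` and one column
#'   per power level, values the minimum detectable differences.
#' @examples
#' min_detectable_difference(20, 1, 20, 1, power = 0.9)  # ~1.025
#' @export
min_detectable_difference <- function(n_a, sd_a, n_b, sd_b,
                                      power = c(0.9, 0.95, 0.99, 0.999),
                                      alpha = 0.05) {
  stopifnot(n_a >= 2, n_b >= 2, all(sd_a > 0), all(sd_b > 0),
            length(sd_a) == length(sd_b))
  if (any(power <= 0 | power >= 1)) stop("power must be in (0, 1)")
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  mult <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  out <- outer(sp * sqrt(1 / n_a + 1 / n_b), mult)
  colnames(out) <- paste0("power_", power)
  rn <- names(sd_a)
  out <- as.data.frame(out)
  if (!is.null(rn)) rownames(out) <- rn
  out
}
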