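par_names <- c("k1", "k2", "b1", "b2", "eps1", "eps2", "mu")

make_groups <- function(seed, shift = 0, n_a = 10, n_b = 10) {
  set.seed(seed)
  a <- matrix(rnorm(n_a * 7, 5), n_a, 7, dimnames = list(NULL, par_names))
  b <- matrix(rnorm(n_b * 7, 5 + shift), n_b, 7,
              dimnames = list(NULL, par_names))
  list(a = a, b = b)
}

test_that("group comparison has the documented structure and corrections", {
  g <- make_groups(1, shift = 3)
  tab <- compare_groups(g$a, g$b, labels = c("EC", "EO"))
  expect_s3_class(tab, "group_comparison")
  expect_equal(nrow(tab), 7)
  expect_equal(tab$p_t_bonf, pmin(1, tab$p_t * 7))
  expect_equal(tab$p_wilcox_bonf, pmin(1, tab$p_wilcox * 7))
  expect_true(all(tab$p_t > 0 & tab$p_t <= 1))
  # large built-in shift: everything significant after correction
  expect_true(all(tab$p_t_bonf < 0.05))
  # Bonferroni caps at 1
  g0 <- make_groups(2, shift = 0)
  tab0 <- compare_groups(g0$a, g0$b)
  expect_true(any(tab0$p_t_bonf == 1))
})

test_that("identical groups give p near 1 and degenerate input warns", {
  x <- matrix(rep(1:6, 7), 6, 7, dimnames = list(NULL, par_names))
  tab <- suppressWarnings(compare_groups(x, x))
  expect_true(all(tab$p_t > 0.99))
  expect_true(all(tab$p_wilcox > 0.9))
  const <- matrix(1, 5, 1, dimnames = list(NULL, "k1"))
  expect_warning(tabc <- compare_groups(const, const), "zero variance")
  expect_true(all(tabc$p_t == 1))
})

test_that("exact Wilcoxon matches full enumeration on separated samples", {
  # all ranks separated: two-sided p = 2 / choose(10, 5) = 2/252
  expect_equal(wilcoxon_ranksum(1:5, 6:10, method = "exact"), 2 / 252,
               tolerance = 1e-12)
})

test_that("normal approximation tracks the exact Wilcoxon p at n = 8 + 8", {
  set.seed(17)
  for (i in 1:100) {
    x <- rnorm(8); y <- rnorm(8, mean = runif(1, 0, 1.5))
    p_exact <- wilcoxon_ranksum(x, y, method = "exact")
    p_norm <- wilcoxon_ranksum(x, y, method = "normal")
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("summary t-test equals the raw-data pooled t-test", {
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(12, 2, 1.5); y <- rnorm(9, 2.5, 0.8)
    ref <- t.test(x, y, var.equal = TRUE)
    out <- t_test_summary(length(x), mean(x), sd(x),
                          length(y), mean(y), sd(y))
    expect_equal(out$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(out$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("minimum detectable difference follows the closed form", {
  # n = 20 + 20, sd 1, alpha 0.05, power 0.9: (1.96 + 1.2816) sqrt(0.1)
  d <- min_detectable_difference(20, 1, 20, 1, power = 0.9)
  expect_equal(d[1, 1], (qnorm(0.975) + qnorm(0.9)) * sqrt(0.1),
               tolerance = 1e-12)
  expect_equal(d[1, 1], 1.025, tolerance = 1e-3)
  # power 0.5 collapses to the significance quantile alone
  d5 <- min_detectable_difference(20, 1, 20, 1, power = 0.5)
  expect_equal(d5[1, 1], qnorm(0.975) * sqrt(0.1), tolerance = 1e-12)
  # doubling both n shrinks the difference by sqrt(2)
  d2 <- min_detectable_difference(40, 1, 40, 1, power = 0.9)
  expect_equal(d[1, 1] / d2[1, 1], sqrt(2), tolerance = 1e-12)
  # strictly increasing in power and pooled SD
  dd <- min_detectable_difference(10, 2, 20, 3,
                                  power = c(0.8, 0.9, 0.99))
  expect_true(all(diff(as.numeric(dd[1, ])) > 0))
  dbig <- min_detectable_difference(10, 4, 20, 6, power = 0.9)
  expect_gt(dbig[1, 1], dd[1, 2])
  expect_error(min_detectable_difference(10, 1, 10, 1, power = 1.2),
               "power")
})
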