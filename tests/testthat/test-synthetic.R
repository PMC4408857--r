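test_that("surrogate spectra realise their target band fractions", {
  for (cond in c("EC-CTL", "EO-CTL", "EC-AD", "EO-AD")) {
    prof <- surrogate_profile(cond)
    blocks <- generate_surrogate_blocks(prof, 4, seed = 11)
    bp <- rowMeans(sapply(blocks, band_powers))
    expect_lt(mean(abs(bp - prof$band_fractions)), 0.03)
  }
  # condition-defining shapes
  ec <- band_powers(generate_surrogate_blocks(surrogate_profile("EC-CTL"),
                                              1, seed = 1)[[1]])
  expect_equal(names(which.max(ec)), "alpha")
  ad <- band_powers(generate_surrogate_blocks(surrogate_profile("EC-AD"),
                                              1, seed = 1)[[1]])
  expect_gte(ad[["theta"]], ad[["alpha"]])
  eo <- band_powers(generate_surrogate_blocks(surrogate_profile("EO-CTL"),
                                              1, seed = 1)[[1]])
  expect_lte(max(eo[2:5]), 0.35)  # flat upper-delta through lower-beta
})

test_that("an all-alpha profile leaks less than 3% outside its band", {
  prof <- surrogate_profile("custom",
                            band_fractions = c(0, 0, 0, 1, 0, 0, 0),
                            noise_floor = 0)
  b <- generate_surrogate_blocks(prof, 1, seed = 2)[[1]]
  # measured at 0.25 Hz resolution so window leakage stays below the
  # construction's own out-of-band content
  expect_gt(band_powers(b, window_s = 4)[["alpha"]], 0.97)
})

test_that("surrogate band fractions converge with duration", {
  prof <- surrogate_profile("EC-CTL")
  err_at <- function(dur, seed) {
    p <- surrogate_profile("EC-CTL", duration = dur)
    mean(sapply(generate_surrogate_blocks(p, 3, seed = seed), function(b) {
      mean(abs(band_powers(b) - prof$band_fractions))
    }))
  }
  expect_lt(err_at(160, 5), err_at(40, 5))
})

test_that("generators are seed-deterministic and well-formed", {
  b1 <- generate_surrogate_blocks(surrogate_profile("EO-AD"), 2, seed = 9)
  b2 <- generate_surrogate_blocks(surrogate_profile("EO-AD"), 2, seed = 9)
  expect_identical(lapply(b1, as.numeric), lapply(b2, as.numeric))
  expect_equal(length(b1[[1]]), 5000L)
  expect_equal(attr(b1[[1]], "condition"), "EO")
  expect_equal(attr(b1[[1]], "group"), "AD")
  m1 <- generate_model_blocks(reference_params("EO-CTL"), 2, seed = 3,
                              duration = 4)
  m2 <- generate_model_blocks(reference_params("EO-CTL"), 2, seed = 3,
                              duration = 4)
  expect_identical(lapply(m1, as.numeric), lapply(m2, as.numeric))
  expect_error(generate_model_blocks(reference_params("EC-CTL"), 1),
               "infeasible")
  expect_equal(generate_surrogate_blocks(surrogate_profile("EC-CTL"), 0),
               list())
  # every generated block passes feature extraction
  for (b in c(b1, m1)) expect_s3_class(feature_vector(b), "feature_vector")
})

test_that("injected artifacts are detectable at the stated rate", {
  blocks <- generate_surrogate_blocks(surrogate_profile("EC-CTL"), 1,
                                      seed = 21)
  b <- blocks[[1]]
  expect_identical(inject_artifacts(b, rate = 0)$block, b)
  hits <- sapply(1:25, function(s) {
    dirty <- inject_artifacts(b, rate = 3, amplitude = 8, width = 12,
                              seed = s)
    mask <- detect_artifacts(dirty$block, robust = TRUE)
    # detected-or-adjacent coverage of truly contaminated peak region
    core <- which(dirty$mask & abs(as.numeric(dirty$block) -
                                     mean(as.numeric(dirty$block))) >
                    4.5 * sd(as.numeric(b)))
    if (!length(core)) return(NA_real_)
    mean(mask[core])
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})

test_that("repair restores sample entropy of the clean block", {
  blocks <- generate_surrogate_blocks(surrogate_profile("EC-CTL"), 1,
                                      seed = 33)
  clean <- blocks[[1]]
  se_clean <- sample_entropy(as.numeric(clean) / sd(clean))
  diffs <- sapply(1:10, function(s) {
    dirty <- inject_artifacts(clean, rate = 3, amplitude = 8, seed = s)
    repaired <- clean_block(dirty$block)
    abs(sample_entropy(as.numeric(repaired) / sd(repaired)) - se_clean)
  })
  expect_lt(mean(diffs), 0.1)
})
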