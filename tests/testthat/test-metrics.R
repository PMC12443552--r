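# SSIM/PSNR against independent oracles, quality banding, the combination
# sweep, and the paired t-test.

test_that("SSIM: self-similarity, symmetry, bound, and the constant-image closed form", {
  set.seed(1)
  x <- array(runif(12^3), c(12, 12, 12))
  expect_equal(ssimVolume(x, x), 1, tolerance = 1e-12)
  y <- array(runif(12^3), c(12, 12, 12))
  expect_equal(ssimVolume(x, y), ssimVolume(y, x), tolerance = 1e-12)
  expect_lte(ssimVolume(x, y), 1)

  # constant images: variance terms vanish, leaving the luminance term
  kap <- 0.4; del <- 0.2; R <- 1
  a <- array(kap, c(10, 10, 10)); b <- array(kap + del, c(10, 10, 10))
  C1 <- (0.01 * R)^2
  closed <- (2 * kap * (kap + del) + C1) / (kap^2 + (kap + del)^2 + C1)
  expect_equal(ssimVolume(a, b, dataRange = R), closed, tolerance = 1e-12)

  expect_error(ssimVolume(x, array(0, c(10, 10, 10))), "grids differ")
  expect_error(ssimVolume(array(0, c(5, 5, 5)), array(0, c(5, 5, 5))),
               "smaller than the SSIM window")
})

test_that("SSIM matches an independent sliding-window implementation", {
  set.seed(2)
  for (i in 1:3) {
    x <- array(runif(16^3), c(16, 16, 16))
    y <- pmin(pmax(x + rnorm(16^3, sd = 0.1), 0), 1)
    expect_equal(ssimVolume(x, y, dataRange = 1),
                 ssimOracle(x, y, dataRange = 1), tolerance = 1e-6)
  }
})

test_that("PSNR follows its closed forms and decreases with noise", {
  x <- array(0, c(8, 8, 8))
  expect_identical(psnrVolume(x, x), Inf)
  y <- array(0.5, c(8, 8, 8))
  expect_equal(psnrVolume(x, y, dataRange = 1), 10 * log10(1 / 0.25),
               tolerance = 1e-10)            # ~6.0206 dB
  one <- array(1, c(8, 8, 8))
  expect_equal(psnrVolume(x, one, dataRange = 1), 0, tolerance = 1e-12)

  set.seed(3)
  base <- array(runif(10^3), c(10, 10, 10))
  noise <- array(rnorm(10^3), c(10, 10, 10))
  p <- vapply(c(0.01, 0.05, 0.1, 0.3),
              function(s) psnrVolume(base, base + s * noise), 0)
  expect_true(all(diff(p) < 0))
})

test_that("PSNR quality bands use the stated boundaries", {
  expect_identical(psnrQualityBand(45), "very_good")
  expect_identical(psnrQualityBand(40), "good")       # boundary -> lower band
  expect_identical(psnrQualityBand(32.76), "good")
  expect_identical(psnrQualityBand(30), "good")
  expect_identical(psnrQualityBand(29.999), "bad")
  expect_identical(psnrQualityBand(20), "bad")
  expect_identical(psnrQualityBand(19.99), "very_bad")
  expect_identical(psnrQualityBand(Inf), "very_good")
  expect_identical(psnrQualityBand(40 + 1e-9), "very_good")
})

test_that("evaluateSubject crops to the brain bounding box and flags identity", {
  subj <- tinyCohort(1, seed = 40)[[1]]
  r <- evaluateSubject(NULL, subj, prediction = targetCBV(subj))
  expect_equal(ssimPercent(r), 100)
  expect_identical(psnrDb(r), Inf)
  expect_identical(qualityBand(r), "very_good")

  # a prediction correct inside the brain but wrong in the background:
  # bbox metrics must differ from whole-volume metrics
  wrong <- volData(targetCBV(subj))
  bg <- volData(subj@volumes$T1) == 0
  wrong[bg] <- 0.8
  pred <- volume3D(wrong, spacing = volSpacing(targetCBV(subj)))
  rBox <- evaluateSubject(NULL, subj, prediction = pred)
  whole <- 100 * ssimVolume(wrong, volData(targetCBV(subj)),
                            dataRange = max(volData(targetCBV(subj))))
  expect_gt(ssimPercent(rBox), whole)

  noCBV <- mriSubject("x", subj@volumes)
  expect_error(evaluateSubject(NULL, noCBV, prediction = pred),
               "no ground-truth CBV")
  model <- initIEDN(tinyIEDNConfig(baseChannels = 2))
  expect_error(evaluateSubject(model, subj,
                               presenceOverride = presenceMask(character())),
               "empty fusion")
})

test_that("the benchmark enumerates 16 (or 17) combinations, all containing ASL-CBF", {
  c16 <- enumerateCombinations()
  expect_length(c16, 16)
  expect_true(all(vapply(c16, function(x) "ASLCBF" %in% x, TRUE)))
  expect_identical(c16[[1]], "ASLCBF")
  sizes <- vapply(c16, length, 1L)
  expect_equal(sum(sizes == 1), 1)              # ASL-CBF alone
  expect_equal(sum(sizes == 2), 4)
  expect_equal(sum(sizes == 3), 6)
  expect_equal(sum(sizes == 4), 4)
  expect_equal(sum(sizes == 5), 1)
  expect_false(any(vapply(c16, function(x) "T1C" %in% x, TRUE)))

  c17 <- enumerateCombinations(includeT1CRow = TRUE)
  expect_length(c17, 17)
  expect_setequal(c17[[17]], c("ASLCBF", "T1", "T2", "ADC", "T1C"))
  expect_identical(comboLabel(c17[[17]]), "ASL-CBF+T1+T2+ADC+T1C")
  # no duplicates
  labels <- vapply(c17, comboLabel, "")
  expect_equal(anyDuplicated(labels), 0L)
})

test_that("sweepCombinations reports per-row statistics consistently", {
  model <- initIEDN(tinyIEDNConfig(baseChannels = 2, seed = 3))
  test2 <- tinyCohort(2, seed = 41)
  rep2 <- sweepCombinations(model, test2, dataRangePolicy = "fixed1")
  df <- comboResults(rep2)
  expect_equal(nrow(df), 16)
  expect_true(all(df$n == 2))
  expect_true(all(df$ssim_sd >= 0))

  # one test subject -> SD exactly 0
  rep1 <- sweepCombinations(model, test2[1], dataRangePolicy = "fixed1")
  expect_true(all(comboResults(rep1)$ssim_sd == 0))

  # the ASL-only row equals a direct single-modality synthesis
  direct <- evaluateSubject(model, test2[[1]],
                            presenceOverride = presenceMask("ASLCBF"),
                            dataRangePolicy = "fixed1")
  expect_equal(comboResults(rep1)$ssim_mean[1], ssimPercent(direct),
               tolerance = 1e-12)

  # per-row mean lies within the per-subject range
  per <- vapply(test2, function(s)
    ssimPercent(evaluateSubject(model, s,
                                presenceOverride = presenceMask("ASLCBF"),
                                dataRangePolicy = "fixed1")), 0)
  expect_gte(df$ssim_mean[1], min(per))
  expect_lte(df$ssim_mean[1], max(per))

  # subjects missing a needed modality are skipped with n adjusted
  mixed <- list(test2[[1]], dropModalities(test2[[2]], "ASLCBF"))
  repM <- suppressMessages(
    sweepCombinations(model, mixed, dataRangePolicy = "fixed1"))
  expect_true(all(comboResults(repM)$n == 1))
})

test_that("pairedTTest reproduces the closed-form example and rejects degenerate input", {
  r <- pairedTTest(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_equal(r$statistic, 3.8729833, tolerance = 1e-6)
  expect_equal(r$parameter, 3)
  expect_equal(r$p.value, 0.0305, tolerance = 2e-3)
  expect_equal(r$meanDifference, 2.5)

  same <- pairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  expect_error(pairedTTest(c(1, 2, 3), c(0, 1, 2)), "zero variance")
  expect_error(pairedTTest(1:3, 1:2), "equal length")
  expect_error(pairedTTest(1, 2), "at least 2")

  # agreement with the reference implementation on non-degenerate data
  set.seed(5)
  a <- rnorm(12); b <- rnorm(12)
  ht <- t.test(a, b, paired = TRUE)
  r2 <- pairedTTest(a, b)
  expect_equal(r2$statistic, unname(ht$statistic), tolerance = 1e-12)
  expect_equal(r2$p.value, ht$p.value, tolerance = 1e-12)
})
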