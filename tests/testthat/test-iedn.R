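# Model core: initialization, encoding, presence-weighted fusion,
# synthesis composition, baseline contracts, checkpoints.

test_that("initIEDN builds one encoder per modality, reproducibly", {
  m1 <- initIEDN(tinyIEDNConfig(modalities = "ASLCBF"))
  expect_length(m1@encoders, 1)
  expect_named(m1@encoders, "ASLCBF")

  a <- initIEDN(tinyIEDNConfig(seed = 42))
  b <- initIEDN(tinyIEDNConfig(seed = 42))
  expect_identical(a@encoders, b@encoders)
  expect_identical(a@decoder, b@decoder)
  d <- initIEDN(tinyIEDNConfig(seed = 43))
  expect_false(identical(a@encoders$T1$conv1.w, d@encoders$T1$conv1.w))
  # encoders share architecture but not weights
  expect_false(identical(a@encoders$T1$conv1.w, a@encoders$T2$conv1.w))

  expect_error(iednConfig(modalities = c("T1", "T1")), "duplicate")
  expect_error(iednConfig(levels = 0), "levels")
})

test_that("encoding reaches the bottleneck resolution and is deterministic", {
  model <- initIEDN(tinyIEDNConfig())
  v <- volume3D(array(runif(16^3), c(16, 16, 16)))
  z <- encodeModality(model, "T1", v)
  expect_equal(dim(latentFeatures(z))[1:3], c(4L, 4L, 4L))  # 16 / 2^2
  z2 <- encodeModality(model, "T1", v)
  expect_identical(latentFeatures(z), latentFeatures(z2))
  expect_error(encodeModality(model, "T1",
                              volume3D(array(0, c(10, 10, 10)))),
               "divisible")
  expect_error(encodeModality(initIEDN(tinyIEDNConfig(modalities = "T1")),
                              "ADC", v), "no encoder")
})

test_that("fuseLatents is the presence-weighted mean and matches a brute-force oracle", {
  mods <- inputModalities()
  shp <- c(2, 2, 2, 3)
  set.seed(8)
  lat <- lapply(mods, function(m) array(rnorm(prod(shp)), shp))
  names(lat) <- mods

  one <- fuseLatents(lat["T1"], presenceMask("T1"))
  expect_identical(latentFeatures(one), lat$T1)

  # all 63 non-empty masks against direct evaluation of sum(a*L)/sum(a)
  worst <- 0
  for (bits in 1:63) {
    present <- mods[bitwAnd(bits, 2^(0:5)) > 0]
    fused <- latentFeatures(fuseLatents(lat, presenceMask(present)))
    stack <- vapply(present, function(m) lat[[m]], lat[[1]])
    direct <- apply(array(stack, c(shp, length(present))), 1:4, sum) /
      length(present)
    worst <- max(worst, max(abs(fused - direct)))
  }
  expect_lt(worst, 1e-12)

  expect_error(fuseLatents(lat, presenceMask(character())), "empty fusion")
  bad <- lat; bad$T2 <- array(0, c(2, 2, 1, 3))
  expect_error(fuseLatents(bad, presenceMask(c("T1", "T2"))),
               "shape mismatch")
  expect_error(fuseLatents(lat["T1"], presenceMask(c("T1", "T2"))),
               "no latent supplied")
})

test_that("fusion is idempotent on identical latents and constant-preserving", {
  shp <- c(2, 2, 2, 4)
  L <- array(rnorm(prod(shp)), shp)
  lat <- list(T1 = L, T2 = L, ADC = L)
  f <- latentFeatures(fuseLatents(lat, presenceMask(c("T1", "T2", "ADC"))))
  expect_equal(f, L, tolerance = 1e-15)
  kap <- lapply(1:4, function(i) array(2.5, shp))
  names(kap) <- c("T1", "T2", "T2FLAIR", "ADC")
  fk <- latentFeatures(fuseLatents(kap, presenceMask(names(kap))))
  expect_true(all(fk == 2.5))
})

test_that("synthesizeCBV equals the manual encode/fuse/decode chain", {
  model <- initIEDN(tinyIEDNConfig(seed = 4))
  subj <- tinyCohort(1, seed = 12)[[1]]
  out <- synthesizeCBV(model, subj)
  lat <- lapply(inputModalities(), function(m)
    encodeModality(model, m, subj@volumes[[m]]))
  names(lat) <- inputModalities()
  fused <- fuseLatents(lat, subjectPresence(subj))
  manual <- pmax(decodeLatent(model, fused), 0)
  expect_identical(volData(out), manual)        # max abs difference 0
  expect_true(min(volData(out)) >= 0)
  expect_equal(dim(volData(out)), dim(volData(subj@volumes$T1)))
})

test_that("presence overrides remove but never add modalities", {
  model <- initIEDN(tinyIEDNConfig(seed = 1))
  subj <- tinyCohort(1, seed = 3)[[1]]
  full <- synthesizeCBV(model, subj)
  same <- synthesizeCBV(model, subj,
                        presenceOverride = subjectPresence(subj))
  expect_identical(volData(full), volData(same))

  expect_error(synthesizeCBV(model, subj,
                             presenceOverride = presenceMask(character())),
               "empty fusion")

  # an override naming a modality the subject lacks is silently masked to 0
  noASL <- dropModalities(subj, "ASLCBF")
  viaOverride <- synthesizeCBV(model, noASL,
                               presenceOverride = presenceMask(
                                 c("T1", "ASLCBF")))
  viaPhysical <- synthesizeCBV(model, noASL,
                               presenceOverride = presenceMask("T1"))
  expect_identical(volData(viaOverride), volData(viaPhysical))
})

test_that("the fixed-combination baseline demands its full combination", {
  cfg <- tinyIEDNConfig(seed = 2)
  edn1 <- initEDN(cfg, "ASLCBF")
  expect_equal(nrow(edn1@encoder$conv1.w), 27 * 1)
  edn5 <- initEDN(cfg, c("ASLCBF", "T1", "T2", "ADC", "T1C"))
  expect_equal(nrow(edn5@encoder$conv1.w), 27 * 5)
  expect_error(initEDN(cfg, character()), "non-empty")

  subj <- tinyCohort(1, seed = 3)[[1]]
  out <- synthesizeCBV(edn5, subj)
  expect_equal(dim(volData(out)), c(16L, 16L, 16L))
  expect_error(synthesizeCBV(edn5, dropModalities(subj, "ASLCBF")),
               "lacks modality")
  expect_error(synthesizeCBV(edn5, subj,
                             presenceOverride = presenceMask("T1")),
               "cannot drop")
})

test_that("checkpoints round-trip weights bit-for-bit and verify their config", {
  tmp <- withr::local_tempdir()
  model <- initIEDN(tinyIEDNConfig(seed = 77))
  p <- file.path(tmp, "ck.rds")
  saveCheckpoint(model, p)
  back <- loadCheckpoint(p)
  expect_identical(back@encoders, model@encoders)
  expect_identical(back@decoder, model@decoder)
  expect_identical(back@config@modalities, model@config@modalities)

  obj <- readRDS(p); obj$hash <- "tampered"; saveRDS(obj, p)
  expect_error(loadCheckpoint(p), "hash mismatch")

  edn <- initEDN(tinyIEDNConfig(seed = 5), c("ASLCBF", "T1"))
  p2 <- file.path(tmp, "edn.rds")
  saveCheckpoint(edn, p2)
  expect_identical(loadCheckpoint(p2)@encoder, edn@encoder)
})
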