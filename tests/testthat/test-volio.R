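# Volume I/O, reslicing, normalization, bounding boxes, cohort manifests.

test_that("NIfTI write/read round-trips data, spacing and origin exactly", {
  tmp <- withr::local_tempdir()
  vz <- volume3D(array(0, c(8, 8, 8)))
  readVolume(writeVolume(vz, file.path(tmp, "zero.nii.gz"))) |>
    volData() |> expect_equal(array(0, c(8, 8, 8)))

  set.seed(11)
  v <- volume3D(array(rnorm(16^3), c(16, 16, 16)),
                spacing = c(0.5, 0.5, 3), origin = c(-10, 4, 2))
  r <- readVolume(writeVolume(v, file.path(tmp, "r.nii.gz")))
  expect_identical(volData(r), volData(v))       # tolerance 0
  expect_equal(volSpacing(r), c(0.5, 0.5, 3))
  expect_equal(volOrigin(r), c(-10, 4, 2))
  expect_identical(volOrientation(r), "RAS")
})

test_that("NaN voxels are zeroed with a warning counting them", {
  tmp <- withr::local_tempdir()
  a <- array(runif(6^3), c(6, 6, 6))
  a[c(3, 50, 100)] <- NaN
  img <- RNifti::asNifti(a)
  img <- RNifti::`sform<-`(img, structure(diag(4), code = 2L))
  RNifti::writeNifti(img, file.path(tmp, "nan.nii.gz"))
  expect_warning(v <- readVolume(file.path(tmp, "nan.nii.gz")),
                 "replaced 3 NaN")
  expect_equal(sum(volData(v)[c(3, 50, 100)]), 0)
  expect_true(all(is.finite(volData(v))))
})

test_that("a flipped-orientation file is reoriented to RAS preserving the voxel-to-world map", {
  tmp <- withr::local_tempdir()
  a <- array(seq_len(4 * 5 * 6) * 1.0, c(4, 5, 6))
  aff <- diag(c(-1, 1, 2, 1))        # LAS with 2 mm slices
  aff[1:3, 4] <- c(3, 1, -2)
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(1, 1, 2)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, file.path(tmp, "las.nii.gz"))
  v <- readVolume(file.path(tmp, "las.nii.gz"))
  expect_identical(volOrientation(v), "RAS")
  expect_equal(volSpacing(v), c(1, 1, 2))
  # world x of voxel 0 was +3 flipped; in RAS the data reverse along x and
  # the origin moves to the old last voxel (3 - 3*1 = 0)
  expect_equal(volOrigin(v), c(0, 1, -2))
  expect_equal(volData(v), a[4:1, , ])
})

test_that("4D files are rejected with a dimensionality error", {
  tmp <- withr::local_tempdir()
  img <- RNifti::asNifti(array(0, c(4, 4, 4, 2)))
  RNifti::writeNifti(img, file.path(tmp, "4d.nii.gz"))

  expect_error(readVolume(file.path(tmp, "4d.nii.gz")), "3D volumes")
  expect_error(readVolume(file.path(tmp, "absent.nii.gz")), "cannot read")
})

test_that("reslicing to the same grid is the identity and constants stay constant", {
  set.seed(2)
  v <- volume3D(array(rnorm(8^3), c(8, 8, 8)), spacing = c(1, 2, 1))
  same <- resliceToReference(v, v)
  expect_equal(volData(same), volData(v), tolerance = 1e-12)

  const <- volume3D(array(5, c(12, 12, 12)), spacing = c(1, 1, 1))
  ref <- volume3D(array(0, c(5, 5, 5)), spacing = c(1.7, 1.3, 2),
                  origin = c(1, 1, 1))
  out <- resliceToReference(const, ref)
  expect_true(all(abs(volData(out) - 5) < 1e-12))
})

test_that("trilinear reslicing matches a per-voxel world-coordinate oracle", {
  set.seed(3)
  src <- volume3D(array(rnorm(16^3), c(16, 16, 16)), spacing = c(1, 1, 1))
  ref <- volume3D(array(0, c(8, 8, 8)), spacing = c(2, 2, 2))
  out <- resliceToReference(src, ref)
  for (idx in list(c(1, 1, 1), c(3, 5, 2), c(8, 8, 8), c(4, 2, 7))) {
    world <- (idx - 1) * volSpacing(ref) + volOrigin(ref)
    expect_equal(volData(out)[idx[1], idx[2], idx[3]],
                 trilinearOracle(src, world), tolerance = 1e-12)
  }
  far <- volume3D(array(1, c(4, 4, 4)), origin = c(1000, 0, 0))
  expect_error(resliceToReference(src, far), "overlap")
})

test_that("nearest-neighbour reslicing picks the closest voxel", {
  a <- array(seq_len(4^3) * 1.0, c(4, 4, 4))
  src <- volume3D(a, spacing = c(2, 2, 2))
  ref <- volume3D(array(0, c(4, 4, 4)), spacing = c(2, 2, 2),
                  origin = c(0.4, 0.4, 0.4))   # closer to the same voxel
  out <- resliceToReference(src, ref, interp = "nearest")
  expect_equal(volData(out), a)
})

test_that("intensity normalization follows its definitions and rejects degenerate input", {
  set.seed(4)
  v <- volume3D(array(rnorm(10^3, mean = 40, sd = 7), c(10, 10, 10)))
  z <- normalizeIntensity(v, "zscore")
  expect_lt(abs(mean(volData(z))), 1e-6)
  expect_lt(abs(sd(volData(z)) - 1), 1e-6)

  expect_error(normalizeIntensity(volume3D(array(3, c(5, 5, 5))), "zscore"),
               "degenerate")

  u <- volume3D(array(runif(12^3, 10, 20), c(12, 12, 12)))
  p <- normalizeIntensity(u, "percentile01")
  expect_equal(min(volData(p)), 0)
  expect_equal(max(volData(p)), 1)
  expect_gte(mean(volData(p) > 0 & volData(p) < 1), 0.97)
  q <- quantile(volData(u), c(0.01, 0.99), names = FALSE)
  expect_equal(volData(p)[2, 2, 2],
               min(max((volData(u)[2, 2, 2] - q[1]) / (q[2] - q[1]), 0), 1))
})

test_that("z-score statistics respect a mask region", {
  set.seed(5)
  v <- volume3D(array(rnorm(8^3, 10), c(8, 8, 8)))
  m <- array(0, c(8, 8, 8)); m[1:4, , ] <- 1
  z <- normalizeIntensity(v, "zscore", mask = volume3D(m))
  expect_lt(abs(mean(volData(z)[m > 0])), 1e-6)
  expect_lt(abs(sd(volData(z)[m > 0]) - 1), 1e-6)
})

test_that("brain bounding box is tight, padded, clipped, and monotone in threshold", {
  a <- array(0, c(10, 10, 10))
  a[4, 5, 6] <- 1                     # 0-based (3, 4, 5)
  bb <- brainBoundingBox(volume3D(a), pad = 0)
  expect_equal(bboxLo(bb), c(3L, 4L, 5L))
  expect_equal(bboxHi(bb), c(4L, 5L, 6L))

  expect_error(brainBoundingBox(volume3D(array(0, c(6, 6, 6)))),
               "empty foreground")

  # ellipsoid support, verified against an exhaustive supra-threshold scan
  d <- c(32, 32, 32); ctr <- (d - 1) / 2; semi <- c(6, 8, 10)
  q <- outer(outer(((seq_len(d[1]) - 1 - ctr[1]) / semi[1])^2,
                   ((seq_len(d[2]) - 1 - ctr[2]) / semi[2])^2, `+`),
             ((seq_len(d[3]) - 1 - ctr[3]) / semi[3])^2, `+`)
  mask <- array(as.numeric(q <= 1), d)
  bb2 <- brainBoundingBox(volume3D(mask), thresholdFraction = 0.5, pad = 0)
  idx <- which(mask > 0.5, arr.ind = TRUE)
  expect_equal(bboxLo(bb2), as.integer(apply(idx, 2, min) - 1))
  expect_equal(bboxHi(bb2), as.integer(apply(idx, 2, max)))

  # raising the threshold never enlarges the box
  set.seed(6)
  noisy <- volume3D(array(runif(20^3)^3, c(20, 20, 20)))
  prev <- brainBoundingBox(noisy, 0.05, pad = 0)
  for (thr in c(0.1, 0.3, 0.5, 0.8)) {
    cur <- brainBoundingBox(noisy, thr, pad = 0)
    expect_true(all(bboxLo(cur) >= bboxLo(prev)) &&
                  all(bboxHi(cur) <= bboxHi(prev)))
    prev <- cur
  }

  # padding is clipped to the volume extent
  bb3 <- brainBoundingBox(volume3D(a), pad = 100)
  expect_equal(bboxLo(bb3), c(0L, 0L, 0L))
  expect_equal(bboxHi(bb3), c(10L, 10L, 10L))
})

test_that("cropVolume extracts the half-open box and advances the origin", {
  a <- array(seq_len(6^3) * 1.0, c(6, 6, 6))
  v <- volume3D(a, spacing = c(2, 2, 2), origin = c(1, 1, 1))
  bb <- boundingBox(c(1, 2, 3), c(4, 5, 6))
  cr <- cropVolume(v, bb)
  expect_equal(dim(volData(cr)), c(3L, 3L, 3L))
  expect_equal(volData(cr), a[2:4, 3:5, 4:6])
  expect_equal(volOrigin(cr), c(1, 1, 1) + c(1, 2, 3) * 2)
})

test_that("cohorts round-trip through manifest CSVs with correct presence", {
  tmp <- withr::local_tempdir()
  cohort <- tinyCohort(2, aslFraction = 0.5, seed = 21)
  manifest <- writeCohort(cohort, tmp)
  back <- loadCohort(manifest)
  expect_length(back, 2)
  expect_setequal(presentModalities(subjectPresence(back[[1]])),
                  inputModalities())
  expect_equal(presenceFlags(subjectPresence(back[[2]]))[["ASLCBF"]], 0L)
  expect_null(back[[2]]@volumes[["ASLCBF"]])
  expect_equal(volData(targetCBV(back[[1]])),
               volData(targetCBV(cohort[[1]])), tolerance = 1e-12)
})

test_that("loadCohort reslices mismatched grids onto the reference modality grid", {
  tmp <- withr::local_tempdir()
  set.seed(9)
  t1 <- volume3D(array(runif(16^3), c(16, 16, 16)), spacing = c(1, 1, 1))
  t2coarse <- volume3D(array(runif(8^3), c(8, 8, 8)), spacing = c(2, 2, 2))
  writeVolume(t1, file.path(tmp, "t1.nii.gz"))
  writeVolume(t2coarse, file.path(tmp, "t2.nii.gz"))
  df <- data.frame(subject_id = "s1", patient_id = "p1", t1 = "t1.nii.gz",
                   t2 = "t2.nii.gz", t2flair = "", adc = "", aslcbf = "",
                   t1c = "", cbv = "", stringsAsFactors = FALSE)
  write.csv(df, file.path(tmp, "manifest.csv"), row.names = FALSE)
  subj <- loadCohort(file.path(tmp, "manifest.csv"))[[1]]
  expect_equal(dim(volData(subj@volumes$T2)), c(16L, 16L, 16L))
  ora <- resliceToReference(t2coarse, t1)
  expect_equal(volData(subj@volumes$T2), volData(ora), tolerance = 1e-10)
})

test_that("manifest errors: duplicate ids and missing files are named", {
  tmp <- withr::local_tempdir()
  df <- data.frame(subject_id = c("a", "a"), patient_id = c("p", "p"),
                   t1 = "x.nii.gz", t2 = "", t2flair = "", adc = "",
                   aslcbf = "", t1c = "", cbv = "", stringsAsFactors = FALSE)
  write.csv(df, file.path(tmp, "m.csv"), row.names = FALSE)
  expect_error(loadCohort(file.path(tmp, "m.csv")), "duplicate subject id")
  df2 <- df[1, ]
  write.csv(df2, file.path(tmp, "m2.csv"), row.names = FALSE)
  expect_error(loadCohort(file.path(tmp, "m2.csv")), "file not found")
})
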