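# Synthetic multi-contrast brain phantom: latent tissue fields (vascularity,
# cellularity, fluid) inside an ellipsoidal brain mask, spherical lesions of
# hyper-/hypo-perfused archetypes, and fixed monotone rendering maps whose
# ground-truth CBV is a known deterministic function of vascularity.

#' PhantomParams: configuration of the phantom cohort generator
#'
#' @slot grid Integer length-3 voxel counts (default 32^3).
#' @slot spacingMm Numeric length-3 voxel size in mm (default 2 mm).
#' @slot nLesions Number of non-overlapping spherical lesions per subject.
#' @slot lesionRadiusRangeMm Numeric length-2 (min, max) lesion radius, mm.
#' @slot noiseSd Named numeric: additive Gaussian noise SD per rendered
#'   modality (post-normalization units), including `CBV`.
#' @slot aslFraction Fraction of subjects that keep their ASL-CBF volume.
#' @slot cbvFraction Fraction of subjects that keep a ground-truth CBV map.
#' @slot seed Integer; the whole cohort is a pure function of the params.
#' @export
setClass("PhantomParams",
  representation(grid = "integer", spacingMm = "numeric",
                 nLesions = "integer", lesionRadiusRangeMm = "numeric",
                 noiseSd = "numeric", aslFraction = "numeric",
                 cbvFraction = "numeric", seed = "integer"))

setValidity("PhantomParams", function(object) {
  msg <- character()
  if (length(object@grid) != 3L || any(object@grid < 16L))
    msg <- c(msg, "grid must be 3 dimensions, each >= 16")
  if (any(object@spacingMm <= 0)) msg <- c(msg, "spacing must be positive")
  if (object@nLesions < 0L) msg <- c(msg, "nLesions must be >= 0")
  if (object@aslFraction < 0 || object@aslFraction > 1)
    msg <- c(msg, "aslFraction must be in [0, 1]")
  if (object@cbvFraction < 0 || object@cbvFraction > 1)
    msg <- c(msg, "cbvFraction must be in [0, 1]")
  if (any(object@noiseSd < 0)) msg <- c(msg, "noiseSd must be >= 0")
  nm <- c(inputModalities(), targetModality())
  if (!identical(names(object@noiseSd), nm))
    msg <- c(msg, "noiseSd must be named by the modalities plus CBV")
  if (length(msg)) msg else TRUE
})

#' Construct PhantomParams
#'
#' `noiseSd` may be a single number: structural modalities and the CBV
#' ground truth then use it directly while ASL-CBF gets twice that value,
#' encoding that ASL carries the perfusion signal but at a lower
#' signal-to-noise ratio than a DSC-derived CBV map.
#'
#' @param grid Voxel counts per axis (default `c(32, 32, 32)`).
#' @param spacingMm Voxel size in mm (default 2 mm isotropic).
#' @param nLesions Lesions per subject (default 2: one hyper-, one
#'   hypo-perfused archetype).
#' @param lesionRadiusRangeMm Lesion radius range in mm (default 4-8 mm).
#' @param noiseSd Scalar noise SD (default 0.02), or a full named vector
#'   over `c(inputModalities(), "CBV")`.
#' @param aslFraction Fraction of subjects keeping ASL (default 1).
#' @param cbvFraction Fraction keeping ground-truth CBV (default 1).
#' @param seed Cohort seed (default 0).
#' @return A [PhantomParams-class].
#' @export
#' @examples
#' phantomParams(noiseSd = 0, aslFraction = 0.5)
phantomParams <- function(grid = c(32, 32, 32), spacingMm = c(2, 2, 2),
                          nLesions = 2L, lesionRadiusRangeMm = c(4, 8),
                          noiseSd = 0.02, aslFraction = 1, cbvFraction = 1,
                          seed = 0L) {
  nm <- c(inputModalities(), targetModality())
  if (length(noiseSd) == 1L) {
    ns <- rep(noiseSd, length(nm))
    names(ns) <- nm
    ns["ASLCBF"] <- 2 * noiseSd
  } else ns <- noiseSd[nm]
  new("PhantomParams", grid = as.integer(grid),
      spacingMm = as.numeric(spacingMm), nLesions = as.integer(nLesions),
      lesionRadiusRangeMm = as.numeric(lesionRadiusRangeMm), noiseSd = ns,
      aslFraction = as.numeric(aslFraction),
      cbvFraction = as.numeric(cbvFraction), seed = as.integer(seed))
}

setMethod("show", "PhantomParams", function(object) {
  cat(sprintf("PhantomParams: %s grid, %s mm, %d lesion(s), seed %d\n",
              paste(object@grid, collapse = "x"),
              paste(object@spacingMm, collapse = "x"),
              object@nLesions, object@seed))
  cat(sprintf("  aslFraction %.2f, cbvFraction %.2f, noise SD %s\n",
              object@aslFraction, object@cbvFraction,
              paste(sprintf("%s=%.3g", names(object@noiseSd), object@noiseSd),
                    collapse = " ")))
})

#' TissueField: latent per-voxel tissue parameters
#'
#' @slot v Vascularity in \[0,1\]; ground-truth CBV is `v^1.2`.
#' @slot c Cellularity in \[0,1\].
#' @slot f Fluid content in \[0,1\].
#' @slot brainMask Binary 3D array (ellipsoidal brain support).
#' @slot lesionMask Integer 3D array: +1 hyperperfused lesion, -1
#'   hypoperfused lesion, 0 elsewhere.
#' @export
setClass("TissueField",
  representation(v = "array", c = "array", f = "array",
                 brainMask = "array", lesionMask = "array"))

setValidity("TissueField", function(object) {
  msg <- character()
  out <- object@brainMask == 0
  for (s in c("v", "c", "f")) {
    fld <- slot(object, s)
    if (min(fld) < 0 || max(fld) > 1)
      msg <- c(msg, paste0(s, " must lie in [0, 1]"))
    if (any(fld[out] != 0))
      msg <- c(msg, paste0(s, " must be 0 outside the brain mask"))
  }
  if (length(msg)) msg else TRUE
})

# separable Gaussian smoothing with renormalized (truncated) boundary kernels
.gaussSmooth3d <- function(a, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  d <- dim(a)
  for (ax in 1:3) {
    n <- d[ax]
    B <- outer(seq_len(n), seq_len(n),
               function(i, j) ifelse(abs(i - j) <= r,
                                     exp(-((i - j)^2) / (2 * sigma^2)), 0))
    B <- B / rowSums(B)
    m <- matrix(aperm(a, c(ax, setdiff(1:3, ax))), n)
    m <- B %*% m
    a <- aperm(array(m, c(n, d[setdiff(1:3, ax)])),
               order(c(ax, setdiff(1:3, ax))))
  }
  a
}

.ellipsoidMask <- function(grid, fraction = 0.6) {
  ctr <- (grid - 1) / 2
  semi <- fraction * grid / 2
  i <- (seq_len(grid[1]) - 1 - ctr[1]) / semi[1]
  j <- (seq_len(grid[2]) - 1 - ctr[2]) / semi[2]
  k <- (seq_len(grid[3]) - 1 - ctr[3]) / semi[3]
  q <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  array(as.numeric(q <= 1), grid)
}

.smoothUnitField <- function(grid, mask, sigma = 2.5) {
  a <- .gaussSmooth3d(array(rnorm(prod(grid)), grid), sigma)
  inside <- mask > 0
  rng <- range(a[inside])
  a <- (a - rng[1]) / (rng[2] - rng[1])
  a[!inside] <- 0
  a
}

# frozen lesion archetype offsets applied to (v, c, f) inside each sphere
.LESION_ARCHETYPES <- list(
  hyper = c(v = +0.6, c = +0.2, f = -0.1),
  hypo  = c(v = -0.6, c = +0.1, f = +0.2))

# internal: consumes the current RNG stream
.makeTissueFieldRNG <- function(params) {
  grid <- params@grid
  mask <- .ellipsoidMask(grid)
  v <- .smoothUnitField(grid, mask)
  cc <- .smoothUnitField(grid, mask)
  f <- .smoothUnitField(grid, mask)
  lesion <- array(0L, grid)
  if (params@nLesions > 0L) {
    radii <- runif(params@nLesions, params@lesionRadiusRangeMm[1],
                   params@lesionRadiusRangeMm[2])
    centers <- matrix(NA_real_, params@nLesions, 3)
    idxMask <- which(mask > 0, arr.ind = TRUE)
    for (j in seq_len(params@nLesions)) {
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        ctr <- idxMask[sample.int(nrow(idxMask), 1L), ] - 1
        ctrMm <- ctr * params@spacingMm
        # sphere must fit inside the brain mask
        rVox <- ceiling(radii[j] / params@spacingMm)
        lo <- pmax(ctr - rVox, 0); hi <- pmin(ctr + rVox, grid - 1)
        sub <- expand.grid(i = lo[1]:hi[1], jj = lo[2]:hi[2], k = lo[3]:hi[3])
        dmm <- sqrt(((sub$i - ctr[1]) * params@spacingMm[1])^2 +
                    ((sub$jj - ctr[2]) * params@spacingMm[2])^2 +
                    ((sub$k - ctr[3]) * params@spacingMm[3])^2)
        inSphere <- sub[dmm <= radii[j], , drop = FALSE]
        idx <- as.matrix(inSphere) + 1L
        if (any(mask[idx] == 0)) next
        if (j > 1) {
          prev <- centers[seq_len(j - 1), , drop = FALSE]
          dPrev <- sqrt(rowSums(sweep(sweep(prev, 2, ctr), 2,
                                      params@spacingMm, `*`)^2))
          if (any(dPrev <= radii[j] + radii[seq_len(j - 1)])) next
        }
        centers[j, ] <- ctr
        arch <- if (j %% 2L == 1L) "hyper" else "hypo"
        off <- .LESION_ARCHETYPES[[arch]]
        v[idx] <- pmin(pmax(v[idx] + off["v"], 0), 1)
        cc[idx] <- pmin(pmax(cc[idx] + off["c"], 0), 1)
        f[idx] <- pmin(pmax(f[idx] + off["f"], 0), 1)
        lesion[idx] <- if (arch == "hyper") 1L else -1L
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place ", params@nLesions,
             " non-overlapping lesions in 1000 attempts")
    }
  }
  new("TissueField", v = v, c = cc, f = f, brainMask = mask,
      lesionMask = lesion)
}

#' Generate a latent tissue field
#'
#' An ellipsoidal brain mask occupying ~60% of each axis, three smooth
#' random fields (vascularity, cellularity, fluid; Gaussian-smoothed white
#' noise, SD 2.5 voxels, min-max rescaled to \[0,1\] inside the mask, 0
#' outside), and `nLesions` non-overlapping spheres alternating between a
#' hyperperfused archetype (vascularity pushed toward 1) and a hypoperfused
#' one (pushed toward 0).
#'
#' @param params A [PhantomParams-class].
#' @param seed Seed for this field; defaults to `params@seed`.
#' @return A [TissueField-class].
#' @export
makeTissueField <- function(params, seed = params@seed) {
  stopifnot(is(params, "PhantomParams"))
  .withSeed(seed, .makeTissueFieldRNG(params))
}

# frozen rendering maps; tests assert against these exact coefficients
.renderNoiseless <- function(field) {
  v <- field@v; cc <- field@c; f <- field@f
  lesionInd <- as.numeric(field@lesionMask != 0L)
  t1 <- 0.3 + 0.5 * cc - 0.2 * f
  list(
    T1      = t1,
    T2      = 0.2 + 0.6 * f,
    T2FLAIR = 0.2 + 0.6 * f * (1 - f),
    ADC     = 0.9 - 0.5 * cc,
    ASLCBF  = v,
    T1C     = t1 + 0.4 * v * lesionInd,
    CBV     = v^1.2)
}

.renderModalitiesRNG <- function(field, params, id, patientId = id) {
  maps <- .renderNoiseless(field)
  inside <- field@brainMask > 0
  vols <- list()
  for (m in names(maps)) {
    a <- maps[[m]]
    sdm <- params@noiseSd[[m]]
    if (sdm > 0) a[inside] <- a[inside] + rnorm(sum(inside), sd = sdm)
    a <- pmin(pmax(a, 0), 1)
    a[!inside] <- 0
    vols[[m]] <- volume3D(a, spacing = params@spacingMm)
  }
  mriSubject(id, vols[inputModalities()], patientId = patientId,
             targetCBV = vols[[targetModality()]])
}

#' Render a tissue field into a multi-contrast subject
#'
#' Applies the module's frozen monotone rendering maps:
#' `T1 = 0.3 + 0.5 c - 0.2 f`, `T2 = 0.2 + 0.6 f`,
#' `T2FLAIR = 0.2 + 0.6 f (1 - f)`, `ADC = 0.9 - 0.5 c`, `ASLCBF = v`,
#' `T1C = T1 + 0.4 v * lesion`, and ground-truth `CBV = v^1.2`, each plus
#' in-mask Gaussian noise of the configured SD, clipped to \[0,1\], zero
#' outside the brain mask.  With `noiseSd = 0` the CBV target equals
#' `v^1.2` exactly.
#'
#' @param field A [TissueField-class].
#' @param params A [PhantomParams-class] (grid must match the field).
#' @param id Subject identifier.
#' @param seed Noise seed; defaults to `params@seed`.
#' @return An [MRISubject-class] with all six input modalities and a
#'   ground-truth CBV, on one grid.
#' @export
renderModalities <- function(field, params, id = "phantom", seed = params@seed) {
  stopifnot(is(field, "TissueField"), is(params, "PhantomParams"))
  if (!identical(dim(field@v), as.integer(params@grid)))
    stop("tissue field grid does not match params grid")
  .withSeed(seed, .renderModalitiesRNG(field, params, id))
}

#' Generate a phantom cohort
#'
#' `nSubjects` phantom patients with fresh tissue fields, rendered into
#' co-registered multi-contrast subjects.  Exactly
#' `round(aslFraction * n)` scans keep their ASL-CBF volume (the leading
#' ones in order) and exactly `round(cbvFraction * n)` keep the
#' ground-truth CBV, emulating a cohort in which perfusion imaging is only
#' available for part of the population.  With `scansPerPatient > 1` every
#' patient is scanned repeatedly (same anatomy, fresh noise), for
#' exercising patient-level splitting.
#'
#' @param params A [PhantomParams-class].
#' @param nSubjects Number of phantom patients (>= 1).
#' @param scansPerPatient Scans per patient (default 1).
#' @return List of [MRISubject-class]; deterministic in `params`.
#' @export
#' @examples
#' cohort <- makeCohort(phantomParams(noiseSd = 0, seed = 1), 2)
#' length(cohort)
makeCohort <- function(params, nSubjects, scansPerPatient = 1L) {
  stopifnot(is(params, "PhantomParams"), nSubjects >= 1)
  .withSeed(params@seed, {
    subjects <- list()
    for (i in seq_len(nSubjects)) {
      field <- .makeTissueFieldRNG(params)
      for (s in seq_len(scansPerPatient)) {
        id <- if (scansPerPatient == 1L) sprintf("phantom_%03d", i)
              else sprintf("phantom_%03d_s%d", i, s)
        subjects[[length(subjects) + 1L]] <-
          .renderModalitiesRNG(field, params, id,
                               patientId = sprintf("pat_%03d", i))
      }
    }
    n <- length(subjects)
    nASL <- round(params@aslFraction * n)
    nCBV <- round(params@cbvFraction * n)
    for (k in seq_len(n)) {
      if (k > nASL) subjects[[k]] <- dropModalities(subjects[[k]], "ASLCBF")
      if (k > nCBV) {
        s <- subjects[[k]]
        subjects[[k]] <- mriSubject(s@id, s@volumes, patientId = s@patientId,
                                    targetCBV = NULL)
      }
    }
    subjects
  })
}
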