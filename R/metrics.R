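# Quantitative evaluation: volumetric SSIM and PSNR over the brain
# bounding box, PSNR quality banding, the modality-combination benchmark
# sweep, and the paired t-test used to compare two models.

#' Volumetric structural similarity index (SSIM)
#'
#' Standard SSIM with stabilizers `C1 = (0.01 * dataRange)^2` and
#' `C2 = (0.03 * dataRange)^2`, computed in 3D with a Gaussian-weighted
#' window (default 7^3 voxels, sigma 1.5) and averaged over all fully
#' contained (valid) window positions.  Symmetric in its two arguments.
#' Values below 0 are possible for anti-correlated inputs and are reported
#' raw; the typical range is \[0, 1\] with 1 iff the inputs are identical.
#'
#' @param x,y [Volume3D-class] objects or bare 3D arrays on one grid, each
#'   extent at least `window`.
#' @param dataRange Positive dynamic range of the data.
#' @param window Odd window width in voxels (default 7).
#' @param sigma Gaussian weighting SD in voxels (default 1.5).
#' @return Mean local SSIM (dimensionless, <= 1).
#' @export
ssimVolume <- function(x, y, dataRange = 1, window = 7L, sigma = 1.5) {
  a <- if (is(x, "Volume3D")) x@data else x
  b <- if (is(y, "Volume3D")) y@data else y
  if (!identical(dim(a), dim(b))) stop("x and y grids differ")
  stopifnot(dataRange > 0, window %% 2 == 1, sigma > 0)
  if (any(dim(a) < window))
    stop("volume extent ", paste(dim(a), collapse = "x"),
         " smaller than the SSIM window (", window, ")")
  k <- exp(-((seq_len(window) - (window + 1) / 2)^2) / (2 * sigma^2))
  k <- k / sum(k)
  filt <- function(z) .sepFilterValid(z, k)
  mx <- filt(a); my <- filt(b)
  vx <- filt(a * a) - mx * mx
  vy <- filt(b * b) - my * my
  cxy <- filt(a * b) - mx * my
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx * mx + my * my + C1) * (vx + vy + C2))
  mean(s)
}

# separable "valid" filtering with a symmetric 1D kernel along each axis
.sepFilterValid <- function(a, k) {
  w <- length(k)
  for (ax in 1:3) {
    d <- dim(a)
    n <- d[ax]; nOut <- n - w + 1L
    B <- matrix(0, nOut, n)
    for (i in seq_len(nOut)) B[i, i:(i + w - 1L)] <- k
    others <- setdiff(1:3, ax)
    m <- matrix(aperm(a, c(ax, others)), n)
    m <- B %*% m
    a <- aperm(array(m, c(nOut, d[others])), order(c(ax, others)))
  }
  a
}

#' Peak signal-to-noise ratio (PSNR)
#'
#' `10 * log10(dataRange^2 / MSE)` in dB.  Identical inputs (MSE = 0) are
#' reported as `Inf`, the distinguished "identical" marker, which maps to
#' the `very_good` quality band.
#'
#' @param x,y [Volume3D-class] objects or bare 3D arrays on one grid.
#' @param dataRange Positive dynamic range of the data.
#' @return PSNR in dB (`Inf` when the volumes are identical).
#' @export
psnrVolume <- function(x, y, dataRange = 1) {
  a <- if (is(x, "Volume3D")) x@data else x
  b <- if (is(y, "Volume3D")) y@data else y
  if (!identical(dim(a), dim(b))) stop("x and y grids differ")
  stopifnot(dataRange > 0)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(dataRange^2 / mse)
}

#' PSNR quality band
#'
#' PSNR above 40 dB is very good, 30 to 40 dB good (acceptable), 20 to
#' 30 dB bad, below 20 dB very bad (unacceptable).  Boundaries belong to
#' the lower band: 40 itself is good, 30 good, 20 bad.  `Inf` (identical
#' volumes) is very good.
#'
#' @param psnrDb PSNR in dB (may be `Inf`).
#' @return One of `"very_good"`, `"good"`, `"bad"`, `"very_bad"`.
#' @export
#' @examples
#' psnrQualityBand(32.76)  # "good"
psnrQualityBand <- function(psnrDb) {
  stopifnot(length(psnrDb) == 1L, !is.na(psnrDb))
  if (psnrDb > 40) "very_good"
  else if (psnrDb >= 30) "good"
  else if (psnrDb >= 20) "bad"
  else "very_bad"
}

#' MetricResult: SSIM/PSNR of one synthetic volume
#'
#' @slot ssimPercent SSIM times 100 (reported on the percent scale).
#' @slot psnrDb PSNR in dB (`Inf` marks identical volumes).
#' @slot qualityBand PSNR band per [psnrQualityBand()].
#' @slot region The [BoundingBox-class] the metrics were computed over.
#' @export
setClass("MetricResult",
  representation(ssimPercent = "numeric", psnrDb = "numeric",
                 qualityBand = "character", region = "BoundingBox"))

setValidity("MetricResult", function(object) {
  msg <- character()
  if (object@ssimPercent > 100 + 1e-9)
    msg <- c(msg, "ssimPercent cannot exceed 100")
  if (!identical(object@qualityBand, psnrQualityBand(object@psnrDb)))
    msg <- c(msg, "qualityBand inconsistent with psnrDb")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MetricResult", function(object) {
  cat(sprintf("MetricResult: SSIM %.2f%%, PSNR %s dB (%s)\n",
              object@ssimPercent,
              if (is.infinite(object@psnrDb)) "Inf (identical)"
              else sprintf("%.2f", object@psnrDb),
              object@qualityBand))
})

#' @rdname evaluateSubject
#' @param x A `MetricResult`.
#' @export
ssimPercent <- function(x) x@ssimPercent

#' @rdname evaluateSubject
#' @export
psnrDb <- function(x) x@psnrDb

#' @rdname evaluateSubject
#' @export
qualityBand <- function(x) x@qualityBand

#' Evaluate synthesis quality for one subject
#'
#' Synthesizes the CBV map (or takes a supplied `prediction`), crops both
#' the synthetic and the ground-truth CBV to the subject's brain bounding
#' box, and computes SSIM and PSNR there.  The dynamic range is the maximum
#' of the ground-truth CBV inside the box (`"gtmax"`, the usual
#' neuroimaging convention) or a fixed 1.0 (`"fixed1"`, for normalized
#' phantoms).
#'
#' @param model An [IEDNModel-class] or [EDNModel-class].
#' @param subject An [MRISubject-class] with a ground-truth CBV.
#' @param presenceOverride Optional [PresenceMask-class] forwarded to
#'   [synthesizeCBV()] (IEDN only).
#' @param dataRangePolicy `"gtmax"` (default) or `"fixed1"`.
#' @param prediction Optional precomputed synthetic CBV [Volume3D-class];
#'   when given the model is not run.
#' @return A [MetricResult-class].
#' @export
evaluateSubject <- function(model, subject, presenceOverride = NULL,
                            dataRangePolicy = c("gtmax", "fixed1"),
                            prediction = NULL) {
  dataRangePolicy <- match.arg(dataRangePolicy)
  if (is.null(subject@targetCBV))
    stop("subject '", subject@id, "' has no ground-truth CBV to evaluate ",
         "against")
  if (is.null(prediction))
    prediction <- synthesizeCBV(model, subject, presenceOverride)
  refMod <- if ("T1" %in% names(subject@volumes)) "T1"
            else names(subject@volumes)[1]
  bb <- brainBoundingBox(subject@volumes[[refMod]])
  predC <- cropVolume(prediction, bb)@data
  gtC <- cropVolume(subject@targetCBV, bb)@data
  R <- if (dataRangePolicy == "gtmax") max(gtC) else 1
  if (R <= 0) stop("degenerate ground truth: non-positive dynamic range")
  s <- ssimVolume(predC, gtC, dataRange = R)
  p <- psnrVolume(predC, gtC, dataRange = R)
  new("MetricResult", ssimPercent = 100 * s, psnrDb = p,
      qualityBand = psnrQualityBand(p), region = bb)
}

.comboLabels <- c(T1 = "T1", T2 = "T2", T2FLAIR = "T2-FLAIR", ADC = "ADC",
                  ASLCBF = "ASL-CBF", T1C = "T1C")

#' Label a modality combination
#'
#' @param combo Character vector of modality codes.
#' @return Single display label, e.g. `"ASL-CBF+T1+T2"`.
#' @export
comboLabel <- function(combo) {
  ord <- c("ASLCBF", "T1", "T2", "T2FLAIR", "ADC", "T1C")
  combo <- ord[ord %in% combo]
  paste(.comboLabels[combo], collapse = "+")
}

#' Enumerate the benchmark modality combinations
#'
#' The 16 combinations are ASL-CBF alone plus ASL-CBF unioned with every
#' non-empty subset of \{T1, T2, T2-FLAIR, ADC\}; the optional 17th row adds
#' the post-contrast combination ASL-CBF+T1+T2+ADC+T1C.  The ordering is
#' frozen (single additions, then pairs, triples, the full set, and the
#' post-contrast row last) so benchmark reports diff cleanly.
#'
#' @param includeT1CRow Add the 17th (post-contrast) combination?
#' @return List of character vectors of modality codes; every combination
#'   contains `ASLCBF`.
#' @export
#' @examples
#' length(enumerateCombinations())       # 16
#' length(enumerateCombinations(TRUE))   # 17
enumerateCombinations <- function(includeT1CRow = FALSE) {
  A <- "ASLCBF"
  combos <- list(
    A,
    c(A, "T2"),
    c(A, "T1"),
    c(A, "T2FLAIR"),
    c(A, "ADC"),
    c(A, "T1", "T2"),
    c(A, "T1", "T2FLAIR"),
    c(A, "T1", "ADC"),
    c(A, "T2FLAIR", "ADC"),
    c(A, "T2", "T2FLAIR"),
    c(A, "T2", "ADC"),
    c(A, "T1", "T2", "T2FLAIR"),
    c(A, "T1", "T2", "ADC"),
    c(A, "T2", "T2FLAIR", "ADC"),
    c(A, "T1", "T2FLAIR", "ADC"),
    c(A, "T1", "T2", "T2FLAIR", "ADC"))
  if (includeT1CRow)
    combos <- c(combos, list(c(A, "T1", "T2", "ADC", "T1C")))
  combos
}

#' ComboReport: the combination-sweep benchmark table
#'
#' One row per modality combination and architecture with the test-set
#' SSIM (percent, mean and SD) and PSNR (dB, mean and SD).
#'
#' @slot results data.frame with columns `combo`, `arch`, `n`,
#'   `ssim_mean`, `ssim_sd`, `psnr_mean`, `psnr_sd`.
#' @export
setClass("ComboReport", representation(results = "data.frame"))

setValidity("ComboReport", function(object) {
  need <- c("combo", "arch", "n", "ssim_mean", "ssim_sd", "psnr_mean",
            "psnr_sd")
  if (!all(need %in% names(object@results)))
    return("results must carry the benchmark columns")
  sds <- c(object@results$ssim_sd, object@results$psnr_sd)
  if (any(!is.na(sds) & sds < 0)) return("SDs must be >= 0")
  TRUE
})

#' @rdname sweepCombinations
#' @param x A `ComboReport`.
#' @export
comboResults <- function(x) x@results

setMethod("show", "ComboReport", function(object) {
  df <- object@results
  cat("ComboReport (mean ± SD over the test set)\n")
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-34s %-5s n=%2d  SSIM %6.2f ± %5.2f %%   PSNR %6.2f ± %5.2f dB\n",
                df$combo[i], df$arch[i], df$n[i], df$ssim_mean[i],
                df$ssim_sd[i], df$psnr_mean[i], df$psnr_sd[i]))
})

#' Run the modality-combination benchmark sweep
#'
#' Evaluates the incrementable model on every benchmark combination by
#' presence override (one model, many combinations) and, optionally, one
#' fixed-combination baseline model per combination.  Test subjects missing
#' a modality a combination needs are skipped for that row, with the row's
#' `n` adjusted.
#'
#' @param iedn A trained [IEDNModel-class].
#' @param testSubjects List of [MRISubject-class] with ground-truth CBV.
#' @param edns Optional named list of trained [EDNModel-class]; names are
#'   [comboLabel()]s of their combinations.
#' @param includeT1CRow Include the 17th (post-contrast) row?
#' @param dataRangePolicy Forwarded to [evaluateSubject()].
#' @return A [ComboReport-class].
#' @export
sweepCombinations <- function(iedn, testSubjects, edns = NULL,
                              includeT1CRow = FALSE,
                              dataRangePolicy = c("gtmax", "fixed1")) {
  dataRangePolicy <- match.arg(dataRangePolicy)
  combos <- enumerateCombinations(includeT1CRow)
  rows <- list()
  evalRow <- function(fn, combo, arch) {
    ss <- c(); pp <- c()
    skipped <- character()
    for (s in testSubjects) {
      if (!all(combo %in% presentModalities(subjectPresence(s)))) {
        skipped <- c(skipped, s@id)
        next
      }
      r <- fn(s)
      ss <- c(ss, r@ssimPercent); pp <- c(pp, r@psnrDb)
    }
    if (length(skipped))
      message("sweep: ", arch, " ", comboLabel(combo), ": skipped ",
              length(skipped), " subject(s) missing a modality")
    data.frame(combo = comboLabel(combo), arch = arch, n = length(ss),
               ssim_mean = if (length(ss)) mean(ss) else NA_real_,
               ssim_sd = if (length(ss) > 1) sd(ss) else
                 if (length(ss) == 1) 0 else NA_real_,
               psnr_mean = if (length(pp)) mean(pp) else NA_real_,
               psnr_sd = if (length(pp) > 1) sd(pp) else
                 if (length(pp) == 1) 0 else NA_real_,
               stringsAsFactors = FALSE)
  }
  for (combo in combos) {
    ov <- presenceMask(combo)
    rows[[length(rows) + 1L]] <- evalRow(function(s)
      evaluateSubject(iedn, s, presenceOverride = ov,
                      dataRangePolicy = dataRangePolicy), combo, "IEDN")
    lbl <- comboLabel(combo)
    if (!is.null(edns) && lbl %in% names(edns))
      rows[[length(rows) + 1L]] <- evalRow(function(s)
        evaluateSubject(edns[[lbl]], s, dataRangePolicy = dataRangePolicy),
        combo, "EDN")
  }
  new("ComboReport", results = do.call(rbind, rows))
}

#' Paired t-test between two models' per-subject scores
#'
#' Classical paired t-test on the element-wise differences with `n - 1`
#' degrees of freedom and a two-sided p-value.  Zero-variance differences
#' are a degenerate error — except the all-identical case, which is
#' reported as t = 0, p = 1.
#'
#' @param a,b Equal-length numeric vectors (n >= 2) of paired scores.
#' @return List with `statistic` (t), `parameter` (df), `p.value`
#'   (two-sided), and `meanDifference` (mean of a - b).
#' @export
#' @examples
#' pairedTTest(c(1, 2, 3, 4), c(0, 0, 0, 0))
pairedTTest <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(statistic = 0, parameter = length(d) - 1L, p.value = 1,
                  meanDifference = 0))
    stop("degenerate input: paired differences have zero variance")
  }
  ht <- t.test(a, b, paired = TRUE)
  list(statistic = unname(ht$statistic), parameter = unname(ht$parameter),
       p.value = ht$p.value, meanDifference = unname(ht$estimate))
}
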