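# Cohort splitting and the MAE/Adam training loops for the incrementable
# network (with modality dropout) and the fixed-combination baseline.

#' TrainConfig: training protocol
#'
#' Defaults follow the reference protocol: 500 epochs, Adam at learning
#' rate 0.001, mean-absolute-error loss, a 3:1 train:test split, no
#' validation set.  `modalityDropout = "random_subset"` thins each training
#' subject's present modalities to a uniformly random non-empty subset every
#' epoch, which is what lets a single incrementable model serve every
#' modality combination at inference.
#'
#' @slot epochs Integer >= 1 (default 500).
#' @slot learningRate Positive real (default 0.001).
#' @slot optimizer `"adam"`.
#' @slot loss `"mae"`.
#' @slot splitRatio Train:test ratio expressed as train parts per one test
#'   part (default 3, i.e. 3:1).
#' @slot splitLevel `"patient"` (default; repeat scans never straddle the
#'   split) or `"subject"` (scan-level).
#' @slot modalityDropout `"random_subset"` or `"off"`.
#' @slot dropoutMinPresent Minimum modalities kept by dropout (default 1).
#' @slot batchSize Subjects per optimizer step (default 1).
#' @slot lossRegion `"bbox"` (brain bounding box, default) or `"whole"`.
#' @slot seed Integer seed controlling dropout and ordering.
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", learningRate = "numeric",
                 optimizer = "character", loss = "character",
                 splitRatio = "numeric", splitLevel = "character",
                 modalityDropout = "character", dropoutMinPresent = "integer",
                 batchSize = "integer", lossRegion = "character",
                 seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@optimizer != "adam") msg <- c(msg, "optimizer must be 'adam'")
  if (object@loss != "mae") msg <- c(msg, "loss must be 'mae'")
  if (!object@splitLevel %in% c("patient", "subject"))
    msg <- c(msg, "splitLevel must be 'patient' or 'subject'")
  if (!object@modalityDropout %in% c("off", "random_subset"))
    msg <- c(msg, "modalityDropout must be 'off' or 'random_subset'")
  if (object@dropoutMinPresent < 1L)
    msg <- c(msg, "dropoutMinPresent must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (!object@lossRegion %in% c("bbox", "whole"))
    msg <- c(msg, "lossRegion must be 'bbox' or 'whole'")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainConfig
#'
#' @param epochs,learningRate,splitRatio,splitLevel,modalityDropout,
#'   dropoutMinPresent,batchSize,lossRegion,seed See [TrainConfig-class].
#' @return A [TrainConfig-class].
#' @export
#' @examples
#' trainConfig(epochs = 10, seed = 1)
trainConfig <- function(epochs = 500L, learningRate = 0.001, splitRatio = 3,
                        splitLevel = "patient",
                        modalityDropout = "random_subset",
                        dropoutMinPresent = 1L, batchSize = 1L,
                        lossRegion = "bbox", seed = 0L) {
  new("TrainConfig", epochs = as.integer(epochs),
      learningRate = as.numeric(learningRate), optimizer = "adam",
      loss = "mae", splitRatio = as.numeric(splitRatio),
      splitLevel = splitLevel, modalityDropout = modalityDropout,
      dropoutMinPresent = as.integer(dropoutMinPresent),
      batchSize = as.integer(batchSize), lossRegion = lossRegion,
      seed = as.integer(seed))
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: %d epochs, Adam lr %g, MAE loss, split %g:1 (%s level)\n",
    object@epochs, object@learningRate, object@splitRatio,
    object@splitLevel))
  cat(sprintf("  modality dropout %s (min %d), batch %d, loss over %s, seed %d\n",
              object@modalityDropout, object@dropoutMinPresent,
              object@batchSize, object@lossRegion, object@seed))
})

#' TrainReport: record of one training run
#'
#' @slot lossHistory Mean training loss per epoch (length = epochs).
#' @slot config The [TrainConfig-class] used.
#' @slot info List: subject ids trained on, exclusions, seeds.
#' @export
setClass("TrainReport",
  representation(lossHistory = "numeric", config = "TrainConfig",
                 info = "list"))

#' @rdname trainIEDN
#' @param report A `TrainReport`.
#' @export
lossHistory <- function(report) report@lossHistory

setMethod("show", "TrainReport", function(object) {
  n <- length(object@lossHistory)
  cat(sprintf("TrainReport: %d epoch(s), loss %0.5f -> %0.5f, %d subject(s)\n",
              n, object@lossHistory[1], object@lossHistory[n],
              length(object@info$subjects)))
})

#' Split a cohort into train and test sets
#'
#' Random partition at the scan (`subject`) or `patient` level; at patient
#' level every scan of a patient lands in the same partition, preventing
#' the leakage that scan-level splitting of repeat scans permits.  The
#' train fraction is `ratio / (ratio + 1)` rounded to the nearest unit.
#'
#' @param cohort List of [MRISubject-class].
#' @param ratio Train parts per one test part (default 3, i.e. 3:1).
#' @param level `"patient"` (default) or `"subject"`.
#' @param seed Integer split seed.
#' @return List with elements `train` and `test` (lists of subjects).
#' @export
splitCohort <- function(cohort, ratio = 3, level = c("patient", "subject"),
                        seed = 0L) {
  level <- match.arg(level)
  units <- if (level == "patient")
    unique(vapply(cohort, patientId, "")) else
    vapply(cohort, subjectId, "")
  if (length(units) < 2L)
    stop("need at least 2 ", level, "-level units to split")
  nTrain <- round(length(units) * ratio / (ratio + 1))
  nTrain <- min(max(nTrain, 1L), length(units) - 1L)
  trainUnits <- .withSeed(seed, sample(units, nTrain))
  inTrain <- if (level == "patient")
    vapply(cohort, patientId, "") %in% trainUnits else
    vapply(cohort, subjectId, "") %in% trainUnits
  list(train = cohort[inTrain], test = cohort[!inTrain])
}

#' Mean absolute error between two volumes
#'
#' @param pred,target [Volume3D-class] objects (or bare arrays) on one grid.
#' @param mask Optional binary volume/array on the same grid; the mean runs
#'   over `mask > 0` only.
#' @return Non-negative scalar, `mean(abs(pred - target))` over the region.
#' @export
maeLoss <- function(pred, target, mask = NULL) {
  p <- if (is(pred, "Volume3D")) pred@data else pred
  t <- if (is(target, "Volume3D")) target@data else target
  if (!identical(dim(p), dim(t)))
    stop("pred and target grids differ")
  if (!is.null(mask)) {
    m <- if (is(mask, "Volume3D")) mask@data else mask
    if (!identical(dim(m), dim(p))) stop("mask grid differs from pred")
    sel <- m > 0
    if (!any(sel)) stop("empty mask: no voxels to average over")
    return(mean(abs(p[sel] - t[sel])))
  }
  mean(abs(p - t))
}

# per-subject precomputation shared by both training loops
.prepTrainingSubject <- function(subject, lossRegion) {
  if (is.null(subject@targetCBV))
    stop("training subject '", subject@id, "' lacks a ground-truth CBV")
  d <- dim(subject@targetCBV@data)
  maskSel <- if (lossRegion == "bbox") {
    refMod <- if ("T1" %in% names(subject@volumes)) "T1"
              else names(subject@volumes)[1]
    bb <- brainBoundingBox(subject@volumes[[refMod]])
    m <- array(FALSE, d)
    m[(bb@lo[1] + 1):bb@hi[1], (bb@lo[2] + 1):bb@hi[2],
      (bb@lo[3] + 1):bb@hi[3]] <- TRUE
    m
  } else array(TRUE, d)
  list(target = subject@targetCBV@data, maskSel = maskSel,
       nMask = sum(maskSel))
}

# MAE loss + gradient over the mask region (gradient zero elsewhere)
.maeGrad <- function(pred, target, maskSel, nMask) {
  diffs <- pred - target
  loss <- sum(abs(diffs[maskSel])) / nMask
  g <- array(0, dim(pred))
  g[maskSel] <- sign(diffs[maskSel]) / nMask
  list(loss = loss, grad = g)
}

# uniform draw among all subsets of `present` with size >= minPresent
.sampleSubset <- function(present, minPresent) {
  n <- length(present)
  if (n <= minPresent) return(present)
  sizes <- minPresent:n
  k <- sizes[sample.int(length(sizes), 1L, prob = choose(n, sizes))]
  present[sort(sample.int(n, k))]
}

#' Train an incrementable encoder-decoder model
#'
#' MAE loss inside each subject's brain bounding box, Adam optimizer,
#' batch-of-one volumes.  With `modalityDropout = "random_subset"` each
#' subject's present modalities are thinned to a uniformly random non-empty
#' subset every epoch (never fabricating an absent modality), so the single
#' model learns every combination; subjects may have heterogeneous
#' availability (e.g. some without ASL).  Fully deterministic given
#' `cfg@seed`.
#'
#' @param model An [IEDNModel-class] (see [initIEDN()]).
#' @param trainSubjects List of [MRISubject-class], all with ground-truth
#'   CBV, volumes normalized and on one grid per subject.
#' @param cfg A [TrainConfig-class].
#' @return List with elements `model` (trained [IEDNModel-class]) and
#'   `report` (a [TrainReport-class]).
#' @export
trainIEDN <- function(model, trainSubjects, cfg) {
  stopifnot(is(model, "IEDNModel"), is(cfg, "TrainConfig"),
            length(trainSubjects) >= 1)
  prep <- lapply(trainSubjects, .prepTrainingSubject, cfg@lossRegion)
  inputs <- lapply(trainSubjects, function(s)
    lapply(s@volumes, .asInputArray))
  presentList <- lapply(trainSubjects, function(s)
    intersect(model@config@modalities,
              presentModalities(subjectPresence(s))))
  for (i in seq_along(trainSubjects)) {
    if (length(presentList[[i]]) == 0L)
      stop("training subject '", trainSubjects[[i]]@id,
           "' has no modality the model owns an encoder for")
    .checkDivisible(dim(prep[[i]]$target), model@config@levels)
  }
  cfgM <- model@config
  encoders <- model@encoders
  decoder <- model@decoder
  state <- .adamInit()
  lossHist <- numeric(cfg@epochs)
  .withSeed(cfg@seed, {
    for (ep in seq_len(cfg@epochs)) {
      epochLoss <- 0
      accEnc <- list(); accDec <- NULL; inBatch <- 0L
      for (i in seq_along(trainSubjects)) {
        use <- presentList[[i]]
        if (cfg@modalityDropout == "random_subset")
          use <- .sampleSubset(use, cfg@dropoutMinPresent)
        encOut <- lapply(use, function(m)
          .encFwd(encoders[[m]], inputs[[i]][[m]], cfgM, keepCache = TRUE))
        names(encOut) <- use
        fused <- Reduce(`+`, lapply(encOut, `[[`, "latent")) / length(use)
        dec <- .decFwd(decoder, fused, cfgM, keepCache = TRUE)
        pred <- dec$y
        dim(pred) <- dim(pred)[1:3]
        lg <- .maeGrad(pred, prep[[i]]$target, prep[[i]]$maskSel,
                       prep[[i]]$nMask)
        epochLoss <- epochLoss + lg$loss
        dy <- lg$grad
        dim(dy) <- c(dim(dy), 1L)
        decBack <- .decBwd(decoder, dec$cache, dy, cfgM)
        accDec <- .addGrads(accDec, decBack$grads)
        dz <- decBack$dx / length(use)   # fusion mean splits the gradient
        for (m in use) {
          eb <- .encBwd(encoders[[m]], encOut[[m]]$cache, dz, cfgM)
          accEnc[[m]] <- .addGrads(accEnc[[m]], eb$grads)
        }
        inBatch <- inBatch + 1L
        if (inBatch == cfg@batchSize || i == length(trainSubjects)) {
          decoder <- .applyAdam(state, "dec", decoder, accDec,
                                cfg@learningRate)
          for (m in names(accEnc))
            encoders[[m]] <- .applyAdam(state, paste0("enc.", m),
                                        encoders[[m]], accEnc[[m]],
                                        cfg@learningRate)
          accEnc <- list(); accDec <- NULL; inBatch <- 0L
        }
      }
      lossHist[ep] <- epochLoss / length(trainSubjects)
    }
  })
  trained <- new("IEDNModel", encoders = encoders, decoder = decoder,
                 config = cfgM)
  report <- new("TrainReport", lossHistory = lossHist, config = cfg,
                info = list(subjects = vapply(trainSubjects, subjectId, ""),
                            arch = "IEDN", excluded = character()))
  list(model = trained, report = report)
}

#' Train a fixed-combination baseline model
#'
#' Same loop as [trainIEDN()] but without modality dropout: only subjects
#' carrying every modality of `model@combo` (and a ground-truth CBV) are
#' eligible; the rest are excluded with a message — exactly the data loss
#' the incrementable design avoids.
#'
#' @param model An [EDNModel-class] (see [initEDN()]).
#' @param trainSubjects List of [MRISubject-class].
#' @param cfg A [TrainConfig-class].
#' @return List with elements `model` and `report`; the report's
#'   `info$excluded` holds the ids of excluded subjects.
#' @export
trainEDN <- function(model, trainSubjects, cfg) {
  stopifnot(is(model, "EDNModel"), is(cfg, "TrainConfig"))
  hasAll <- vapply(trainSubjects, function(s)
    !is.null(s@targetCBV) &&
      all(model@combo %in% presentModalities(subjectPresence(s))), TRUE)
  excluded <- vapply(trainSubjects[!hasAll], subjectId, "")
  eligible <- trainSubjects[hasAll]
  if (length(excluded))
    message("trainEDN: excluded ", length(excluded),
            " subject(s) missing a combination modality or the CBV target")
  if (length(eligible) == 0L)
    stop("no eligible training subjects for combination ",
         paste(model@combo, collapse = "+"))
  prep <- lapply(eligible, .prepTrainingSubject, cfg@lossRegion)
  inputs <- lapply(eligible, .stackCombo, model@combo)
  for (i in seq_along(eligible))
    .checkDivisible(dim(prep[[i]]$target), model@config@levels)
  cfgM <- model@config
  enc <- model@encoder
  dec <- model@decoder
  state <- .adamInit()
  lossHist <- numeric(cfg@epochs)
  .withSeed(cfg@seed, {
    for (ep in seq_len(cfg@epochs)) {
      epochLoss <- 0
      accE <- NULL; accD <- NULL; inBatch <- 0L
      for (i in seq_along(eligible)) {
        ef <- .encFwd(enc, inputs[[i]], cfgM, keepCache = TRUE)
        df <- .decFwd(dec, ef$latent, cfgM, keepCache = TRUE)
        pred <- df$y
        dim(pred) <- dim(pred)[1:3]
        lg <- .maeGrad(pred, prep[[i]]$target, prep[[i]]$maskSel,
                       prep[[i]]$nMask)
        epochLoss <- epochLoss + lg$loss
        dy <- lg$grad
        dim(dy) <- c(dim(dy), 1L)
        db <- .decBwd(dec, df$cache, dy, cfgM)
        eb <- .encBwd(enc, ef$cache, db$dx, cfgM)
        accD <- .addGrads(accD, db$grads)
        accE <- .addGrads(accE, eb$grads)
        inBatch <- inBatch + 1L
        if (inBatch == cfg@batchSize || i == length(eligible)) {
          dec <- .applyAdam(state, "dec", dec, accD, cfg@learningRate)
          enc <- .applyAdam(state, "enc", enc, accE, cfg@learningRate)
          accE <- NULL; accD <- NULL; inBatch <- 0L
        }
      }
      lossHist[ep] <- epochLoss / length(eligible)
    }
  })
  trained <- new("EDNModel", combo = model@combo, encoder = enc,
                 decoder = dec, config = cfgM)
  report <- new("TrainReport", lossHistory = lossHist, config = cfg,
                info = list(subjects = vapply(eligible, subjectId, ""),
                            arch = "EDN", excluded = unname(excluded)))
  list(model = trained, report = report)
}
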