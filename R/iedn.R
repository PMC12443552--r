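# The incrementable encoder-decoder network: per-modality encoders, the
# presence-weighted latent fusion rule, the shared CBV decoder, and the
# fixed-combination baseline encoder-decoder.

#' IEDNConfig: network hyperparameters
#'
#' @slot modalities Ordered character vector of input modality codes the
#'   model owns encoders for (duplicate-free, non-empty).
#' @slot levels Number of down/up-sampling stages; input grid dimensions
#'   must be divisible by `2^levels`.
#' @slot baseChannels Channel count at the first stage; channels double per
#'   level and the bottleneck has `baseChannels * 2^levels` channels.
#' @slot kernel Spatial kernel size of the same-size convolutions (3).
#' @slot norm Feature normalization: `"instance"` or `"none"`.
#' @slot seed Integer seed for weight initialization.
#' @export
setClass("IEDNConfig",
  representation(modalities = "character", levels = "integer",
                 baseChannels = "integer", kernel = "integer",
                 norm = "character", seed = "integer"))

setValidity("IEDNConfig", function(object) {
  msg <- character()
  if (length(object@modalities) == 0L)
    msg <- c(msg, "modalities must be non-empty")
  if (anyDuplicated(object@modalities))
    msg <- c(msg, "modalities must be duplicate-free")
  bad <- setdiff(object@modalities, inputModalities())
  if (length(bad))
    msg <- c(msg, paste("unknown modality:", paste(bad, collapse = ", ")))
  if (object@levels < 1L) msg <- c(msg, "levels must be >= 1")
  if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
  if (object@kernel != 3L) msg <- c(msg, "only kernel = 3 is supported")
  if (!object@norm %in% c("instance", "none"))
    msg <- c(msg, "norm must be 'instance' or 'none'")
  if (length(msg)) msg else TRUE
})

#' Construct an IEDNConfig
#'
#' @param modalities Input modalities to own encoders for; default all six.
#' @param levels Down/up-sampling stages (default 3).
#' @param baseChannels First-stage channel count (default 16).
#' @param norm `"instance"` (default; suits batch-of-one 3D training) or
#'   `"none"`.
#' @param seed Weight-initialization seed (default 0).
#' @return An [IEDNConfig-class].
#' @export
#' @examples
#' iednConfig(levels = 2, baseChannels = 8)
iednConfig <- function(modalities = inputModalities(), levels = 3L,
                       baseChannels = 16L, norm = "instance", seed = 0L) {
  new("IEDNConfig", modalities = modalities, levels = as.integer(levels),
      baseChannels = as.integer(baseChannels), kernel = 3L, norm = norm,
      seed = as.integer(seed))
}

setMethod("show", "IEDNConfig", function(object) {
  cat(sprintf("IEDNConfig: %d level(s), base %d channels, %s norm, seed %d\n",
              object@levels, object@baseChannels, object@norm, object@seed))
  cat("  modalities:", paste(object@modalities, collapse = " + "), "\n")
})

.configHash <- function(cfg, what = "IEDN", extra = "") {
  paste(what, paste(cfg@modalities, collapse = ","), cfg@levels,
        cfg@baseChannels, cfg@kernel, cfg@norm, cfg@seed, extra, sep = "|")
}

#' IEDNModel: encoders, fusion contract, shared decoder
#'
#' One convolutional encoder per configured modality (shared architecture,
#' independent weights) and a single decoder.  A subject's CBV map is
#' estimated by encoding every present modality, averaging the bottleneck
#' feature maps weighted by the presence flags, and decoding the average.
#'
#' @slot encoders Named list (one per modality) of parameter lists.
#' @slot decoder Parameter list of the shared decoder.
#' @slot config The [IEDNConfig-class] the model was built from.
#' @export
setClass("IEDNModel",
  representation(encoders = "list", decoder = "list", config = "IEDNConfig"))

setValidity("IEDNModel", function(object) {
  if (!identical(names(object@encoders), object@config@modalities))
    return("exactly one encoder per configured modality, in order")
  TRUE
})

setMethod("show", "IEDNModel", function(object) {
  np <- sum(vapply(object@encoders,
                   function(e) sum(vapply(e, length, 1L)), 1L)) +
    sum(vapply(object@decoder, length, 1L))
  cat(sprintf("IEDNModel: %d encoder(s) + shared decoder, %d parameters\n",
              length(object@encoders), np))
  show(object@config)
})

#' @rdname iednConfig
#' @param x A model or config object.
#' @export
modelConfig <- function(x) x@config

#' Initialize an IEDN model
#'
#' Builds one encoder per configured modality (same architecture,
#' independently initialized weights) plus the shared decoder.  He-normal
#' initialization, fully reproducible from `config@seed`.
#'
#' @param config An [IEDNConfig-class].
#' @return An [IEDNModel-class].
#' @export
#' @examples
#' m <- initIEDN(iednConfig(modalities = "ASLCBF", levels = 2,
#'                          baseChannels = 4))
initIEDN <- function(config) {
  stopifnot(is(config, "IEDNConfig"))
  .withSeed(config@seed, {
    encoders <- lapply(config@modalities,
                       function(m) .initEncoderParams(1L, config))
    names(encoders) <- config@modalities
    decoder <- .initDecoderParams(config)
    new("IEDNModel", encoders = encoders, decoder = decoder, config = config)
  })
}

#' EDNModel: fixed-combination baseline encoder-decoder
#'
#' The non-incrementable baseline: a single encoder over channel-stacked
#' inputs for one fixed modality combination, plus a decoder of the same
#' architecture as the IEDN's.  It cannot tolerate a missing modality —
#' the limitation the incrementable design removes.
#'
#' @slot combo Character vector, the fixed modality combination.
#' @slot encoder Parameter list of the stacked-input encoder.
#' @slot decoder Parameter list of the decoder.
#' @slot config The [IEDNConfig-class] used (levels/channels match IEDN).
#' @export
setClass("EDNModel",
  representation(combo = "character", encoder = "list", decoder = "list",
                 config = "IEDNConfig"))

#' Initialize a fixed-combination baseline model
#'
#' @param config An [IEDNConfig-class]; levels and channel widths are shared
#'   with [initIEDN()] so comparisons are architecture-matched.
#' @param combo Non-empty subset of [inputModalities()]; the encoder's
#'   input channel count equals `length(combo)`.
#' @return An [EDNModel-class].
#' @export
initEDN <- function(config, combo) {
  stopifnot(is(config, "IEDNConfig"))
  .checkModalities(combo)
  if (length(combo) == 0L) stop("combo must be non-empty")
  if (anyDuplicated(combo)) stop("combo must be duplicate-free")
  combo <- inputModalities()[inputModalities() %in% combo]  # canonical order
  .withSeed(config@seed, {
    enc <- .initEncoderParams(length(combo), config)
    dec <- .initDecoderParams(config)
    new("EDNModel", combo = combo, encoder = enc, decoder = dec,
        config = config)
  })
}

setMethod("show", "EDNModel", function(object) {
  cat("EDNModel (fixed combination):",
      paste(object@combo, collapse = " + "), "\n")
  show(object@config)
})

# ---------------------------------------------------------------------------
# Latent maps and fusion

#' LatentMap: bottleneck features of one modality (or the fusion)
#'
#' @slot features 4D numeric array (3 spatial axes x channels) at the
#'   bottleneck resolution.
#' @slot source Modality code the features came from, or `"fused"`.
#' @export
setClass("LatentMap",
  representation(features = "array", source = "character"))

setValidity("LatentMap", function(object) {
  if (length(dim(object@features)) != 4L)
    return("features must be a 4D array")
  if (!all(is.finite(object@features)))
    return("features must be finite")
  TRUE
})

#' @rdname encodeModality
#' @param x A `LatentMap`.
#' @export
latentFeatures <- function(x) x@features

setMethod("show", "LatentMap", function(object) {
  d <- dim(object@features)
  cat(sprintf("LatentMap from '%s': %dx%dx%d spatial, %d channels\n",
              object@source, d[1], d[2], d[3], d[4]))
})

.asInputArray <- function(vol) {
  dat <- if (is(vol, "Volume3D")) vol@data else vol
  d <- dim(dat)
  if (length(d) != 3L) stop("input volume must be 3D")
  dim(dat) <- c(d, 1L)
  dat
}

.checkDivisible <- function(d, levels) {
  if (any(d %% 2^levels != 0))
    stop("grid dimensions (", paste(d, collapse = "x"),
         ") must be divisible by 2^levels = ", 2^levels)
}

#' Encode one modality to its latent map
#'
#' Runs the modality's encoder on a normalized volume and returns the
#' bottleneck feature map.  Deterministic for fixed weights (instance norm
#' has no training/inference distinction).
#'
#' @param model An [IEDNModel-class].
#' @param m Modality code owned by the model.
#' @param vol A normalized [Volume3D-class] (or bare 3D array) whose grid
#'   dimensions are divisible by `2^levels`.
#' @return A [LatentMap-class]; each spatial extent is the input extent
#'   divided by `2^levels`.
#' @export
encodeModality <- function(model, m, vol) {
  stopifnot(is(model, "IEDNModel"))
  if (!m %in% names(model@encoders))
    stop("model has no encoder for modality '", m, "'")
  x <- .asInputArray(vol)
  .checkDivisible(dim(x)[1:3], model@config@levels)
  z <- .encFwd(model@encoders[[m]], x, model@config)$latent
  new("LatentMap", features = z, source = m)
}

#' Fuse latent maps by presence-weighted averaging
#'
#' The incrementable fusion rule: the element-wise mean of the latent maps
#' of the present modalities,
#' `sum_m a_m E_m(S_m) / sum_m a_m` with binary availability flags `a_m`.
#' Absent modalities contribute nothing and their latents need not exist.
#'
#' @param latents Named list of [LatentMap-class] (or bare 4D arrays),
#'   containing at least every present modality.
#' @param presence A [PresenceMask-class] with at least one flag set.
#' @return A [LatentMap-class] with `source = "fused"`.
#' @export
fuseLatents <- function(latents, presence) {
  stopifnot(is(presence, "PresenceMask"))
  pres <- presentModalities(presence)
  if (length(pres) == 0L)
    stop("empty fusion: at least one modality must be present")
  missing <- setdiff(pres, names(latents))
  if (length(missing))
    stop("no latent supplied for present modality: ",
         paste(missing, collapse = ", "))
  feats <- lapply(latents[pres], function(l)
    if (is(l, "LatentMap")) l@features else l)
  d0 <- dim(feats[[1]])
  for (f in feats)
    if (!identical(dim(f), d0))
      stop("latent shape mismatch across modalities")
  fused <- Reduce(`+`, feats) / length(feats)
  new("LatentMap", features = fused, source = "fused")
}

#' Decode a (fused) latent map to a CBV volume array
#'
#' @param model An [IEDNModel-class] or [EDNModel-class].
#' @param latent A [LatentMap-class] or bare 4D array.
#' @return 3D numeric array of unclipped decoder output.
#' @export
decodeLatent <- function(model, latent) {
  z <- if (is(latent, "LatentMap")) latent@features else latent
  y <- .decFwd(model@decoder, z, model@config)$y
  dim(y) <- dim(y)[1:3]
  y
}

.effectivePresence <- function(subject, presenceOverride) {
  pres <- subjectPresence(subject)
  if (!is.null(presenceOverride)) {
    stopifnot(is(presenceOverride, "PresenceMask"))
    # the override can only remove modalities, never add them
    pres <- .maskIntersect(pres, presenceOverride)
  }
  pres
}

#' Synthesize a CBV map for a subject
#'
#' For an [IEDNModel-class]: encodes every effectively present modality,
#' fuses the latents by presence-weighted averaging, decodes, and clips the
#' result at zero (CBV is non-negative; clipping is applied at inference
#' only, never inside the training loss).  `presenceOverride` intersects
#' the subject's own presence mask — it can remove modalities (the
#' "set a_m = 0" experiment) but never add one the subject lacks.
#'
#' For an [EDNModel-class]: the subject must carry every modality of the
#' model's fixed combination; a missing one is an error, since the baseline
#' cannot drop inputs.
#'
#' @param model An [IEDNModel-class] or [EDNModel-class].
#' @param subject An [MRISubject-class] with normalized volumes on one grid.
#' @param presenceOverride Optional [PresenceMask-class] (IEDN only).
#' @return A [Volume3D-class] synthetic CBV map on the subject's grid.
#' @export
setGeneric("synthesizeCBV",
           function(model, subject, presenceOverride = NULL)
             standardGeneric("synthesizeCBV"))

#' @rdname synthesizeCBV
#' @export
setMethod("synthesizeCBV", "IEDNModel",
function(model, subject, presenceOverride = NULL) {
  stopifnot(is(subject, "MRISubject"))
  pres <- .effectivePresence(subject, presenceOverride)
  use <- intersect(names(model@encoders), presentModalities(pres))
  if (length(use) == 0L)
    stop("empty fusion: at least one modality must be present")
  latents <- lapply(use, function(m)
    encodeModality(model, m, subject@volumes[[m]]))
  names(latents) <- use
  fused <- fuseLatents(latents, presenceMask(use))
  y <- decodeLatent(model, fused)
  ref <- subject@volumes[[use[1]]]
  volume3D(pmax(y, 0), spacing = ref@spacing, origin = ref@origin,
           orientation = ref@orientation)
})

#' @rdname synthesizeCBV
#' @export
setMethod("synthesizeCBV", "EDNModel",
function(model, subject, presenceOverride = NULL) {
  stopifnot(is(subject, "MRISubject"))
  if (!is.null(presenceOverride))
    stop("the fixed-combination baseline cannot drop inputs; ",
         "presenceOverride is only meaningful for IEDNModel")
  missing <- setdiff(model@combo, presentModalities(subjectPresence(subject)))
  if (length(missing))
    stop("subject '", subject@id, "' lacks modality ",
         paste(missing, collapse = ", "),
         " required by the fixed combination")
  x <- .stackCombo(subject, model@combo)
  .checkDivisible(dim(x)[1:3], model@config@levels)
  z <- .encFwd(model@encoder, x, model@config)$latent
  y <- .decFwd(model@decoder, z, model@config)$y
  dim(y) <- dim(y)[1:3]
  ref <- subject@volumes[[model@combo[1]]]
  volume3D(pmax(y, 0), spacing = ref@spacing, origin = ref@origin,
           orientation = ref@orientation)
})

.stackCombo <- function(subject, combo) {
  d <- dim(subject@volumes[[combo[1]]]@data)
  x <- array(0, c(d, length(combo)))
  for (i in seq_along(combo)) x[, , , i] <- subject@volumes[[combo[i]]]@data
  x
}

# ---------------------------------------------------------------------------
# Checkpoints

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the weights, the full config
#' (including modality order), and a config hash that is verified on load.
#'
#' @param model An [IEDNModel-class] or [EDNModel-class].
#' @param path Output file path.
#' @return `saveCheckpoint` returns the path invisibly; `loadCheckpoint`
#'   returns the reconstructed model.
#' @export
saveCheckpoint <- function(model, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (is(model, "IEDNModel")) {
    obj <- list(kind = "IEDN", config = model@config,
                encoders = model@encoders, decoder = model@decoder,
                hash = .configHash(model@config, "IEDN"))
  } else if (is(model, "EDNModel")) {
    obj <- list(kind = "EDN", config = model@config, combo = model@combo,
                encoder = model@encoder, decoder = model@decoder,
                hash = .configHash(model@config, "EDN",
                                   paste(model@combo, collapse = ",")))
  } else stop("not a model object")
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (obj$kind == "IEDN") {
    if (!identical(obj$hash, .configHash(obj$config, "IEDN")))
      stop("checkpoint config hash mismatch")
    new("IEDNModel", encoders = obj$encoders, decoder = obj$decoder,
        config = obj$config)
  } else if (obj$kind == "EDN") {
    if (!identical(obj$hash, .configHash(obj$config, "EDN",
                                         paste(obj$combo, collapse = ","))))
      stop("checkpoint config hash mismatch")
    new("EDNModel", combo = obj$combo, encoder = obj$encoder,
        decoder = obj$decoder, config = obj$config)
  } else stop("unrecognized checkpoint kind")
}
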