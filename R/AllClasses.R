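#' @useDynLib synthCBV, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rnorm runif sd quantile pt t.test
#' @importFrom utils read.csv write.csv head
NULL

#' Input modality universe
#'
#' The six input modality codes the network can consume.  `CBV` is the
#' synthesis target and is never an input.
#'
#' @return Character vector of the six input modality codes, in canonical
#'   order: `T1`, `T2`, `T2FLAIR`, `ADC`, `ASLCBF`, `T1C`.
#' @export
#' @examples
#' inputModalities()
inputModalities <- function() c("T1", "T2", "T2FLAIR", "ADC", "ASLCBF", "T1C")

#' @rdname inputModalities
#' @export
targetModality <- function() "CBV"

.checkModalities <- function(m, allowCBV = FALSE) {
  universe <- inputModalities()
  if (allowCBV) universe <- c(universe, targetModality())
  bad <- setdiff(m, universe)
  if (length(bad))
    stop("unknown modality code(s): ", paste(bad, collapse = ", "))
  invisible(m)
}

# ---------------------------------------------------------------------------
# Volume3D

#' Volume3D: a 3D scalar image with grid geometry
#'
#' The atom shared by all modalities: a 3D array of finite intensities plus
#' voxel spacing (mm), world-space origin of voxel (0,0,0) (mm), and an
#' axis-orientation tag (canonical is RAS: +x right, +y anterior,
#' +z superior).  Voxel indices are 0-based in all world-coordinate maths.
#'
#' @slot data 3D numeric array, all values finite.
#' @slot spacing Numeric length-3, strictly positive voxel size in mm.
#' @slot origin Numeric length-3, world position of voxel (0,0,0) in mm.
#' @slot orientation Single string, axis convention tag (e.g. "RAS").
#' @export
setClass("Volume3D",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 orientation = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), orientation = "RAS"))

setValidity("Volume3D", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must have exactly 3 axes")
  else if (any(dim(object@data) < 1L))
    msg <- c(msg, "every axis must have length >= 1")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "all intensities must be finite")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (length(object@orientation) != 1L)
    msg <- c(msg, "orientation must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a Volume3D
#'
#' @param data 3D numeric array of finite intensities.
#' @param spacing Voxel size in mm per axis (default 1 mm isotropic).
#' @param origin World position of voxel (0,0,0) in mm (default the origin).
#' @param orientation Axis convention tag; the package works in "RAS".
#' @return A [Volume3D-class] object.
#' @export
#' @examples
#' v <- volume3D(array(0, c(8, 8, 8)), spacing = c(1, 1, 2))
#' dim(volData(v))
volume3D <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     orientation = "RAS") {
  new("Volume3D", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

#' @rdname volume3D
#' @param x A `Volume3D`.
#' @export
volData <- function(x) x@data

#' @rdname volume3D
#' @export
volSpacing <- function(x) x@spacing

#' @rdname volume3D
#' @export
volOrigin <- function(x) x@origin

#' @rdname volume3D
#' @export
volOrientation <- function(x) x@orientation

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume3D %dx%dx%d voxels, spacing (%g, %g, %g) mm, %s\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], object@orientation))
  cat(sprintf("  origin (%g, %g, %g) mm, intensity range [%g, %g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@data), max(object@data)))
})

.sameGrid <- function(a, b, tol = 1e-6) {
  identical(dim(a@data), dim(b@data)) &&
    all(abs(a@spacing - b@spacing) < tol) &&
    all(abs(a@origin - b@origin) < tol) &&
    identical(a@orientation, b@orientation)
}

# ---------------------------------------------------------------------------
# BoundingBox

#' BoundingBox: a 0-based half-open voxel box
#'
#' `lo` is inclusive and `hi` exclusive, both 0-based, so the box covers
#' voxel indices `lo[k] .. hi[k]-1` on axis k and its extent is `hi - lo`.
#'
#' @slot lo Integer length-3, inclusive lower corner (0-based).
#' @slot hi Integer length-3, exclusive upper corner.
#' @export
setClass("BoundingBox", representation(lo = "integer", hi = "integer"))

setValidity("BoundingBox", function(object) {
  msg <- character()
  if (length(object@lo) != 3L || length(object@hi) != 3L)
    msg <- c(msg, "lo and hi must each have length 3")
  else {
    if (any(object@lo < 0L)) msg <- c(msg, "lo must be non-negative")
    if (any(object@lo >= object@hi))
      msg <- c(msg, "lo[k] < hi[k] required on every axis")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BoundingBox
#'
#' @param lo Inclusive 0-based lower corner (length 3).
#' @param hi Exclusive upper corner (length 3).
#' @return A [BoundingBox-class].
#' @export
#' @examples
#' boundingBox(c(3, 4, 5), c(4, 5, 6))  # a single voxel
boundingBox <- function(lo, hi) {
  new("BoundingBox", lo = as.integer(lo), hi = as.integer(hi))
}

#' @rdname boundingBox
#' @param x A `BoundingBox`.
#' @export
bboxLo <- function(x) x@lo

#' @rdname boundingBox
#' @export
bboxHi <- function(x) x@hi

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox [%s) x [%s) x [%s)  (0-based, half-open)\n",
              paste(object@lo[1], object@hi[1], sep = ", "),
              paste(object@lo[2], object@hi[2], sep = ", "),
              paste(object@lo[3], object@hi[3], sep = ", ")))
})

# ---------------------------------------------------------------------------
# PresenceMask

#' PresenceMask: per-modality availability flags
#'
#' Binary availability indicators over the input-modality universe: flag 1
#' means the modality is present, 0 absent.  Fusion averages only over
#' modalities with flag 1, so a flag of 0 removes the modality from the
#' model without retraining.
#'
#' @slot flags Named integer vector in \{0,1\} over [inputModalities()].
#' @export
setClass("PresenceMask", representation(flags = "integer"))

setValidity("PresenceMask", function(object) {
  m <- inputModalities()
  if (!identical(names(object@flags), m))
    return("flags must be named exactly by inputModalities(), in order")
  if (!all(object@flags %in% c(0L, 1L)))
    return("flags must be 0 or 1")
  TRUE
})

#' Construct a PresenceMask
#'
#' @param present Character vector of modality codes that are present.
#' @return A [PresenceMask-class] with flag 1 for each listed modality.
#' @export
#' @examples
#' presenceMask(c("T1", "ASLCBF"))
presenceMask <- function(present = character()) {
  .checkModalities(present)
  m <- inputModalities()
  flags <- as.integer(m %in% present)
  names(flags) <- m
  new("PresenceMask", flags = flags)
}

#' @rdname presenceMask
#' @param x A `PresenceMask`.
#' @export
presentModalities <- function(x) names(x@flags)[x@flags == 1L]

#' @rdname presenceMask
#' @export
presenceFlags <- function(x) x@flags

setMethod("show", "PresenceMask", function(object) {
  p <- presentModalities(object)
  cat("PresenceMask:", if (length(p)) paste(p, collapse = " + ")
      else "<none present>", "\n")
})

# intersection: flags can only be removed, never added
.maskIntersect <- function(a, b) {
  new("PresenceMask", flags = a@flags * b@flags)
}

# ---------------------------------------------------------------------------
# MRISubject

#' MRISubject: one co-registered scan session
#'
#' A mapping modality -> [Volume3D-class] for the modalities acquired at one
#' session, a [PresenceMask-class], and an optional ground-truth CBV map.
#' Several subjects (scans) may share one `patientId`.
#'
#' @slot id Scan identifier, unique within a cohort.
#' @slot patientId Patient identifier (repeat scans share it).
#' @slot volumes Named list of `Volume3D`, one per present modality.
#' @slot presence A `PresenceMask` consistent with `volumes`.
#' @slot targetCBV A `Volume3D` ground-truth CBV map, or `NULL`.
#' @export
setClass("MRISubject",
  representation(id = "character", patientId = "character",
                 volumes = "list", presence = "PresenceMask",
                 targetCBV = "ANY"))

setValidity("MRISubject", function(object) {
  msg <- character()
  nm <- names(object@volumes)
  if (length(object@volumes) && is.null(nm))
    return("volumes must be a named list")
  bad <- setdiff(nm, inputModalities())
  if (length(bad))
    msg <- c(msg, paste("unknown modality in volumes:",
                        paste(bad, collapse = ", ")))
  pres <- presentModalities(object@presence)
  if (!setequal(nm, pres))
    msg <- c(msg, "presence flag must be 1 iff a volume is stored")
  if (!is.null(object@targetCBV) && !is(object@targetCBV, "Volume3D"))
    msg <- c(msg, "targetCBV must be a Volume3D or NULL")
  if (length(msg)) msg else TRUE
})

#' Construct an MRISubject
#'
#' @param id Scan identifier.
#' @param volumes Named list of [Volume3D-class], names are modality codes.
#' @param patientId Patient identifier; defaults to `id`.
#' @param targetCBV Optional ground-truth CBV [Volume3D-class].
#' @return An [MRISubject-class]; the presence mask is derived from
#'   `names(volumes)`.
#' @export
mriSubject <- function(id, volumes, patientId = id, targetCBV = NULL) {
  new("MRISubject", id = as.character(id), patientId = as.character(patientId),
      volumes = volumes, presence = presenceMask(names(volumes)),
      targetCBV = targetCBV)
}

#' @rdname mriSubject
#' @param x An `MRISubject`.
#' @export
subjectId <- function(x) x@id

#' @rdname mriSubject
#' @export
patientId <- function(x) x@patientId

#' @rdname mriSubject
#' @export
subjectVolumes <- function(x) x@volumes

#' @rdname mriSubject
#' @export
subjectPresence <- function(x) x@presence

#' @rdname mriSubject
#' @export
targetCBV <- function(x) x@targetCBV

#' Drop modalities from a subject
#'
#' Returns a copy of the subject with the given modalities physically
#' removed (volume dropped, presence flag set to 0).
#'
#' @param x An [MRISubject-class].
#' @param drop Character vector of modality codes to remove.
#' @return An [MRISubject-class] without the dropped modalities.
#' @export
dropModalities <- function(x, drop) {
  .checkModalities(drop)
  keep <- setdiff(names(x@volumes), drop)
  mriSubject(x@id, x@volumes[keep], patientId = x@patientId,
             targetCBV = x@targetCBV)
}

setMethod("show", "MRISubject", function(object) {
  cat(sprintf("MRISubject '%s' (patient '%s')\n", object@id, object@patientId))
  cat("  modalities:", paste(presentModalities(object@presence),
                             collapse = " + "), "\n")
  cat("  ground-truth CBV:", if (is.null(object@targetCBV)) "absent"
      else "present", "\n")
  if (length(object@volumes)) {
    d <- dim(object@volumes[[1]]@data)
    cat(sprintf("  grid %dx%dx%d\n", d[1], d[2], d[3]))
  }
})
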