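# Volume I/O, reslicing, normalization, bounding boxes, cohort manifests.

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file, reorients it to the canonical RAS convention,
#' and returns a [Volume3D-class].  NaN voxels (common in ADC/ASL maps as
#' background fill) are replaced by 0 with a warning stating the count.
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @return A [Volume3D-class] in RAS orientation.  Spacing is taken from the
#'   stored transform, the origin is the world position of voxel (0,0,0).
#' @seealso [writeVolume()] for the inverse; the pair round-trips
#'   data/spacing/origin exactly.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  if (length(dim(img)) != 3L)
    stop("volume '", path, "' has ", length(dim(img)),
         " dimensions; 3D volumes required (split 4D files first)")
  RNifti::orientation(img) <- "RAS"
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  origin <- xf[1:3, 4]
  dat <- array(as.numeric(img), dim(img))
  nNaN <- sum(is.nan(dat))
  if (nNaN > 0) {
    dat[is.nan(dat)] <- 0
    warning("replaced ", nNaN, " NaN voxel(s) with 0 in '", path, "'")
  }
  if (any(!is.finite(dat)))
    stop("volume '", path, "' contains non-finite (Inf) intensities")
  volume3D(dat, spacing = spacing, origin = origin)
}

#' Write a Volume3D to NIfTI
#'
#' Writes the volume with an affine encoding its spacing, origin and RAS
#' orientation, such that [readVolume()] recovers data, spacing and origin
#' exactly.
#'
#' @param vol A [Volume3D-class].
#' @param path Output path (`.nii` or `.nii.gz`); the parent directory is
#'   created if needed.
#' @return The path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "Volume3D"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  img <- RNifti::asNifti(vol@data)
  aff <- diag(c(vol@spacing, 1))
  aff[1:3, 4] <- vol@origin
  RNifti::pixdim(img) <- vol@spacing
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  ok <- tryCatch({RNifti::writeNifti(img, path); TRUE},
                 error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop("cannot write NIfTI file: ", path)
  invisible(path)
}

# world coordinate of 0-based voxel index along each axis (RAS, diagonal affine)
.voxelToWorld <- function(vol, idx0) {
  sweep(sweep(idx0, 2, vol@spacing, `*`), 2, vol@origin, `+`)
}

#' Reslice a volume onto a reference grid
#'
#' Samples `vol` at the world-space voxel centres of `ref`, returning a
#' volume with exactly the reference grid (shape, spacing, origin,
#' orientation).  Voxels of the reference grid outside the support of `vol`
#' are set to 0.
#'
#' @param vol Source [Volume3D-class].
#' @param ref Reference [Volume3D-class] supplying the target grid.
#' @param interp `"trilinear"` (images) or `"nearest"` (label masks).
#' @return A [Volume3D-class] on `ref`'s grid.
#' @export
resliceToReference <- function(vol, ref, interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(is(vol, "Volume3D"), is(ref, "Volume3D"))
  dv <- dim(vol@data); dr <- dim(ref@data)
  # world extents (voxel-centre based) must overlap
  loV <- vol@origin; hiV <- vol@origin + (dv - 1) * vol@spacing
  loR <- ref@origin; hiR <- ref@origin + (dr - 1) * ref@spacing
  if (any(hiV < loR) || any(loV > hiR))
    stop("no world-space overlap between volume and reference grid")
  # continuous source voxel coordinate of every reference voxel centre
  g <- lapply(1:3, function(k) {
    (ref@origin[k] + (seq_len(dr[k]) - 1) * ref@spacing[k] - vol@origin[k]) /
      vol@spacing[k]
  })
  cx <- rep(g[[1]], times = dr[2] * dr[3])
  cy <- rep(rep(g[[2]], each = dr[1]), times = dr[3])
  cz <- rep(g[[3]], each = dr[1] * dr[2])
  if (interp == "nearest") {
    ix <- round(cx); iy <- round(cy); iz <- round(cz)
    inside <- ix >= 0 & ix <= dv[1] - 1 & iy >= 0 & iy <= dv[2] - 1 &
      iz >= 0 & iz <= dv[3] - 1
    out <- numeric(length(cx))
    out[inside] <- vol@data[cbind(ix[inside] + 1, iy[inside] + 1,
                                  iz[inside] + 1)]
  } else {
    inside <- cx >= 0 & cx <= dv[1] - 1 & cy >= 0 & cy <= dv[2] - 1 &
      cz >= 0 & cz <= dv[3] - 1
    x0 <- pmin(floor(cx), dv[1] - 2); y0 <- pmin(floor(cy), dv[2] - 2)
    z0 <- pmin(floor(cz), dv[3] - 2)
    x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
    fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
    v <- function(ox, oy, oz)
      vol@data[cbind(x0 + ox + 1, y0 + oy + 1, z0 + oz + 1)]
    out <- (1 - fx) * (1 - fy) * (1 - fz) * v(0, 0, 0) +
      fx * (1 - fy) * (1 - fz) * v(1, 0, 0) +
      (1 - fx) * fy * (1 - fz) * v(0, 1, 0) +
      fx * fy * (1 - fz) * v(1, 1, 0) +
      (1 - fx) * (1 - fy) * fz * v(0, 0, 1) +
      fx * (1 - fy) * fz * v(1, 0, 1) +
      (1 - fx) * fy * fz * v(0, 1, 1) +
      fx * fy * fz * v(1, 1, 1)
    out[!inside] <- 0
  }
  volume3D(array(out, dr), spacing = ref@spacing, origin = ref@origin,
           orientation = ref@orientation)
}

#' Normalize volume intensities
#'
#' `zscore` maps the volume to mean 0 / SD 1 over the mask region (or the
#' whole volume); `percentile01` maps the 1st/99th percentiles to 0/1 and
#' clips to \[0, 1\] — robust to hyperintense lesions, and the package
#' default for input modalities.
#'
#' @param vol A [Volume3D-class].
#' @param method `"percentile01"` (default) or `"zscore"`.
#' @param mask Optional binary [Volume3D-class] on the same grid; statistics
#'   are computed over mask > 0 but the transform is applied everywhere.
#' @return A normalized [Volume3D-class] on the same grid.
#' @export
normalizeIntensity <- function(vol, method = c("percentile01", "zscore"),
                               mask = NULL) {
  method <- match.arg(method)
  stopifnot(is(vol, "Volume3D"))
  vals <- vol@data
  if (!is.null(mask)) {
    stopifnot(is(mask, "Volume3D"))
    if (!identical(dim(mask@data), dim(vol@data)))
      stop("mask grid does not match volume grid")
    sel <- vol@data[mask@data > 0]
  } else sel <- as.vector(vol@data)
  if (method == "zscore") {
    s <- sd(sel)
    if (!is.finite(s) || s <= 0)
      stop("degenerate input: constant intensities, z-score undefined")
    out <- (vals - mean(sel)) / s
  } else {
    q <- quantile(sel, c(0.01, 0.99), names = FALSE, type = 7)
    if (q[2] <= q[1])
      stop("degenerate input: 1st and 99th percentiles coincide")
    out <- pmin(pmax((vals - q[1]) / (q[2] - q[1]), 0), 1)
  }
  volume3D(out, spacing = vol@spacing, origin = vol@origin,
           orientation = vol@orientation)
}

#' Brain bounding box of a volume
#'
#' The tightest 0-based half-open box containing every voxel whose intensity
#' exceeds `thresholdFraction * max(vol)`, expanded by `pad` voxels per side
#' and clipped to the volume extent.  This is the evaluation region used for
#' SSIM/PSNR and the training-loss region.
#'
#' @param vol A [Volume3D-class] (conventionally the T1 volume).
#' @param thresholdFraction Foreground threshold as a fraction of the
#'   maximum intensity, in (0, 1).  Default 0.1.
#' @param pad Non-negative integer padding in voxels per side.  Default 2.
#' @return A [BoundingBox-class].
#' @export
brainBoundingBox <- function(vol, thresholdFraction = 0.1, pad = 2L) {
  stopifnot(is(vol, "Volume3D"), thresholdFraction > 0, thresholdFraction < 1,
            pad >= 0)
  d <- dim(vol@data)
  thr <- thresholdFraction * max(vol@data)
  idx <- which(vol@data > thr, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("empty foreground: no voxel exceeds ", signif(thr, 4))
  lo <- pmax(apply(idx, 2, min) - 1L - pad, 0L)         # to 0-based
  hi <- pmin(apply(idx, 2, max) + pad, d)               # exclusive
  boundingBox(lo, hi)
}

#' Crop a volume to a bounding box
#'
#' @param vol A [Volume3D-class].
#' @param bbox A [BoundingBox-class] (0-based half-open) within the volume.
#' @return The cropped [Volume3D-class]; the origin is advanced so world
#'   coordinates are preserved.
#' @export
cropVolume <- function(vol, bbox) {
  stopifnot(is(vol, "Volume3D"), is(bbox, "BoundingBox"))
  d <- dim(vol@data)
  if (any(bbox@hi > d)) stop("bounding box exceeds volume extent")
  dat <- vol@data[(bbox@lo[1] + 1):bbox@hi[1],
                  (bbox@lo[2] + 1):bbox@hi[2],
                  (bbox@lo[3] + 1):bbox@hi[3], drop = FALSE]
  volume3D(dat, spacing = vol@spacing,
           origin = vol@origin + bbox@lo * vol@spacing,
           orientation = vol@orientation)
}

# ---------------------------------------------------------------------------
# Cohort manifests

.manifestColumns <- function() {
  c("subject_id", "patient_id", "t1", "t2", "t2flair", "adc", "aslcbf",
    "t1c", "cbv")
}

.modalityColumn <- function(m) {
  c(T1 = "t1", T2 = "t2", T2FLAIR = "t2flair", ADC = "adc",
    ASLCBF = "aslcbf", T1C = "t1c", CBV = "cbv")[[m]]
}

#' Read a cohort manifest CSV
#'
#' The manifest has columns `subject_id, patient_id, t1, t2, t2flair, adc,
#' aslcbf, t1c, cbv`; an empty cell means that modality is absent.  Paths
#' are interpreted relative to the manifest's directory.
#'
#' @param path Path to the manifest CSV.
#' @return A data.frame with absolute file paths and one row per subject.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(.manifestColumns(), names(df))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject id(s) in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  base <- dirname(normalizePath(path))
  for (col in setdiff(.manifestColumns(), c("subject_id", "patient_id"))) {
    nz <- !is.na(df[[col]]) & nzchar(df[[col]])
    df[[col]][!nz] <- ""
    df[[col]][nz] <- file.path(base, df[[col]][nz])
  }
  df
}

#' Load a cohort of subjects from a manifest
#'
#' Reads every listed volume, reslices each subject's modalities onto its
#' reference-modality grid (trilinear), and returns a list of
#' [MRISubject-class].  Subjects without a ground-truth CBV are allowed;
#' they can be synthesized from but not used for supervised training.
#'
#' @param manifest Path to a manifest CSV, or a data.frame as returned by
#'   [readManifest()].
#' @param referenceModality Modality whose grid all volumes are resliced to;
#'   default `"T1"`.
#' @return List of [MRISubject-class], in manifest order.
#' @export
loadCohort <- function(manifest, referenceModality = "T1") {
  .checkModalities(referenceModality)
  df <- if (is.character(manifest)) readManifest(manifest) else manifest
  refCol <- .modalityColumn(referenceModality)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    sid <- row$subject_id
    if (!nzchar(row[[refCol]]))
      stop("subject '", sid, "' lacks the reference modality ",
           referenceModality)
    vols <- list()
    for (m in inputModalities()) {
      p <- row[[.modalityColumn(m)]]
      if (!nzchar(p)) next
      if (!file.exists(p))
        stop("subject '", sid, "', modality ", m, ": file not found: ", p)
      vols[[m]] <- readVolume(p)
    }
    ref <- vols[[referenceModality]]
    for (m in names(vols))
      if (!.sameGrid(vols[[m]], ref))
        vols[[m]] <- resliceToReference(vols[[m]], ref)
    cbv <- NULL
    if (nzchar(row$cbv)) {
      if (!file.exists(row$cbv))
        stop("subject '", sid, "', modality CBV: file not found: ", row$cbv)
      cbv <- readVolume(row$cbv)
      if (!.sameGrid(cbv, ref)) cbv <- resliceToReference(cbv, ref)
    }
    pid <- if (nzchar(row$patient_id)) row$patient_id else sid
    mriSubject(sid, vols, patientId = pid, targetCBV = cbv)
  })
}

#' Write a cohort to NIfTI files plus a manifest CSV
#'
#' The on-disk layout is indistinguishable from a real cohort: one NIfTI
#' per modality per subject and a manifest CSV in [readManifest()] format.
#'
#' @param cohort List of [MRISubject-class].
#' @param dir Output directory (created if needed).
#' @return Path to the written manifest CSV, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    row <- stats::setNames(as.list(rep("", length(.manifestColumns()))),
                           .manifestColumns())
    row$subject_id <- s@id
    row$patient_id <- s@patientId
    for (m in names(s@volumes)) {
      fn <- sprintf("%s_%s.nii.gz", s@id, tolower(m))
      writeVolume(s@volumes[[m]], file.path(dir, fn))
      row[[.modalityColumn(m)]] <- fn
    }
    if (!is.null(s@targetCBV)) {
      fn <- sprintf("%s_cbv.nii.gz", s@id)
      writeVolume(s@targetCBV, file.path(dir, fn))
      row$cbv <- fn
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  out <- file.path(dir, "manifest.csv")
  write.csv(df, out, row.names = FALSE)
  invisible(out)
}
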