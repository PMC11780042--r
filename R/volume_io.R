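# Reading, writing and resampling of CT volumes, plus annotation sidecars.
#
# Canonical frame: after loading, voxel axis 1 spans right-left, axis 2
# anterior-posterior, axis 3 inferior-superior, with increasing slice index
# toward the patient's head (NIfTI "RAS"). All downstream coordinates are
# 0-based voxel indices in this frame; physical positions in mm are
# index * spacing, relative to the centre of voxel (0,0,0).

#' Construct a CT volume
#'
#' @param voxels 3D numeric array of Hounsfield units in the canonical
#'   right-left x anterior-posterior x inferior-superior axis order.
#' @param spacing numeric length-3, voxel spacing in mm (all positive).
#' @param subject subject identifier.
#' @return an object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `orientation` (always "RAS") and `subject`.
#' @export
ct_volume <- function(voxels, spacing, subject = "anonymous") {
  stopifnot(length(dim(voxels)) == 3L, length(spacing) == 3L)
  spacing <- as.numeric(spacing)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing components must be strictly positive")
  if (any(!is.finite(voxels)))
    stop("HU values must be finite")
  rng <- range(voxels)
  if (rng[1] < -1100 || rng[2] > 4000)
    warning(sprintf("HU values outside plausible range [-1100, 4000]: [%g, %g]",
                    rng[1], rng[2]))
  structure(list(voxels = voxels, spacing = spacing,
                 orientation = "RAS", subject = subject),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s: %s voxels @ %s mm (%s)\n", x$subject,
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$orientation))
  invisible(x)
}

xform_spacing <- function(img) {
  m <- RNifti::xform(img)
  sqrt(colSums(m[1:3, 1:3]^2))
}

#' Load a CT volume from NIfTI or a DICOM series directory
#'
#' NIfTI images are reoriented to the canonical RAS frame using their
#' qform/sform; DICOM series are sorted by the projection of
#' ImagePositionPatient onto the slice normal and rescale slope/intercept are
#' applied so that voxel values are HU.
#'
#' @param path a `.nii`/`.nii.gz` file or a directory containing one DICOM
#'   series.
#' @param subject subject identifier (defaults to the file/directory name).
#' @return a [ct_volume()].
#' @export
load_volume <- function(path, subject = NULL) {
  if (!file.exists(path))
    stop("cannot read volume: ", path)
  if (is.null(subject))
    subject <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (dir.exists(path))
    return(load_dicom_series(path, subject = subject))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D image, got ", length(dim(img)), "D: ", path)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0 || hdr$sform_code > 0)
    RNifti::orientation(img) <- "RAS"
  spacing <- xform_spacing(img)
  if (any(spacing == 0))
    spacing <- abs(RNifti::pixdim(img))[1:3]
  if (any(spacing == 0))
    stop("missing spacing metadata in ", path)
  vox <- as.array(img)
  attributes(vox) <- list(dim = dim(vox))
  ct_volume(vox, spacing, subject = subject)
}

#' Write a CT volume as NIfTI
#'
#' @param vol a [ct_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$voxels)
  m <- diag(c(vol$spacing, 1))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 1L))
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume to isotropic voxels
#'
#' Trilinear interpolation onto an isotropic grid. Output voxel (i,j,k)
#' (0-based) lies at the same physical position `index * target_spacing` (mm
#' from the first voxel centre), so predicted coordinates map back to the
#' input grid by a pure scale factor per axis.
#'
#' @param vol a [ct_volume()].
#' @param target_spacing isotropic voxel size in mm (default 1).
#' @return a [ct_volume()] with equal spacing on all axes.
#' @export
resample_isotropic <- function(vol, target_spacing = 1) {
  stopifnot(inherits(vol, "ct_volume"), target_spacing > 0)
  d <- dim(vol$voxels)
  if (all(abs(vol$spacing - target_spacing) < 1e-9))
    return(vol)
  nd <- round((d - 1) * vol$spacing / target_spacing) + 1
  if (any(nd < 2))
    stop("resampling to ", target_spacing,
         " mm would produce a degenerate volume (", paste(nd, collapse = "x"), ")")
  s <- target_spacing / vol$spacing
  vox <- resample_trilinear_cpp(vol$voxels, nd[1], nd[2], nd[3], s[1], s[2], s[3])
  out <- ct_volume(vox, rep(target_spacing, 3), subject = vol$subject)
  out
}

#' Create an annotation with L1/L3 centres and optional slice masks
#'
#' @param l1_center,l3_center 0-based voxel coordinates (i, j, k) in the
#'   canonical frame; L1 must be superior to L3 (larger k).
#' @param l1_mask,l3_mask optional [label_mask()] objects for the axial slices
#'   at the corresponding centres.
#' @param subject subject identifier.
#' @return an object of class `annotation`.
#' @export
annotation <- function(l1_center, l3_center, l1_mask = NULL, l3_mask = NULL,
                       subject = "anonymous") {
  l1_center <- as.numeric(l1_center); l3_center <- as.numeric(l3_center)
  stopifnot(length(l1_center) == 3L, length(l3_center) == 3L)
  if (l1_center[3] <= l3_center[3])
    stop("L1 centre must be superior to L3 centre (larger slice index)")
  structure(list(l1_center = l1_center, l3_center = l3_center,
                 l1_mask = l1_mask, l3_mask = l3_mask, subject = subject),
            class = "annotation")
}

#' Read / write annotation JSON sidecars
#'
#' The sidecar stores the two centres as 0-based voxel coordinates and,
#' optionally, relative paths of NIfTI label-mask images:
#' `{"l1_center": [i,j,k], "l3_center": [i,j,k], "l1_mask": "...", ...}`.
#'
#' @param ann an [annotation()].
#' @param path JSON file path; masks are written next to it.
#' @return `load_annotation` returns an [annotation()].
#' @export
save_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "annotation"))
  obj <- list(l1_center = ann$l1_center, l3_center = ann$l3_center,
              subject = ann$subject)
  for (lv in c("l1", "l3")) {
    m <- ann[[paste0(lv, "_mask")]]
    if (!is.null(m)) {
      mpath <- sub("\\.json$", paste0("_", lv, "_mask.nii.gz"), path)
      img <- RNifti::asNifti(array(as.integer(m$labels), c(dim(m$labels), 1L)))
      RNifti::writeNifti(img, mpath)
      obj[[paste0(lv, "_mask")]] <- basename(mpath)
      obj[[paste0(lv, "_classes")]] <- m$classes
    }
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_annotation
#' @export
load_annotation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  masks <- list(l1 = NULL, l3 = NULL)
  for (lv in c("l1", "l3")) {
    mp <- obj[[paste0(lv, "_mask")]]
    if (!is.null(mp)) {
      arr <- as.array(RNifti::readNifti(file.path(dirname(path), mp)))
      if (length(dim(arr)) == 3L) arr <- arr[, , 1]
      masks[[lv]] <- label_mask(matrix(as.integer(arr), nrow = nrow(arr)),
                                level = toupper(lv),
                                classes = unlist(obj[[paste0(lv, "_classes")]]))
    }
  }
  annotation(unlist(obj$l1_center), unlist(obj$l3_center),
             l1_mask = masks$l1, l3_mask = masks$l3,
             subject = if (is.null(obj$subject)) "anonymous" else obj$subject)
}
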