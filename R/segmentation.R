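# Axial-slice segmentation at the L1 and L3 levels: slice extraction onto a
# fixed grid, per-level HU windowing, U-Net inference, and Dice scoring.

#' Class vocabularies of the two segmentation tasks
#'
#' L1 slices are segmented into background / trabecular / cortical bone;
#' L3 slices into background / skeletal muscle (SMA) / visceral (VAT) /
#' subcutaneous (SAT) adipose tissue. Label integers are the 0-based position
#' in these vectors.
#'
#' @param level "L1" or "L3".
#' @return character vector of class names, background first.
#' @export
level_classes <- function(level) {
  switch(level,
         L1 = c("background", "trabecular", "cortical"),
         L3 = c("background", "sma", "vat", "sat"),
         stop("unknown level: ", level))
}

#' Construct an axial slice for segmentation
#'
#' @param hu 2D HU matrix (right-left x anterior-posterior).
#' @param spacing pixel spacing in mm, length 2.
#' @param level "L1" or "L3".
#' @param subject subject identifier.
#' @return a `slab_slice`.
#' @export
slab_slice <- function(hu, spacing, level, subject = "anonymous") {
  stopifnot(is.matrix(hu), length(spacing) == 2L, all(spacing > 0))
  level <- match.arg(level, c("L1", "L3"))
  structure(list(hu = hu, spacing = as.numeric(spacing), level = level,
                 subject = subject),
            class = "slab_slice")
}

#' Extract an axial slice from a volume onto a fixed square grid
#'
#' The slice at 0-based index `k` is centre-padded with air (-1024 HU) or
#' centre-cropped to `grid` x `grid` pixels (512 for clinical CT; smaller
#' grids for reduced-resolution phantoms).
#'
#' @param vol a [ct_volume()].
#' @param k 0-based axial slice index.
#' @param level "L1" or "L3".
#' @param grid output grid size (default 512).
#' @return a [slab_slice()].
#' @export
extract_axial_slice <- function(vol, k, level, grid = 512L) {
  d <- dim(vol$voxels)
  if (k < 0 || k > d[3] - 1) stop("slice index out of range: ", k)
  m <- vol$voxels[, , k + 1]
  out <- matrix(-1024, grid, grid)
  src <- pmin(d[1:2], grid)
  off_in <- floor((d[1:2] - src) / 2)
  off_out <- floor((grid - src) / 2)
  out[off_out[1] + seq_len(src[1]), off_out[2] + seq_len(src[2])] <-
    m[off_in[1] + seq_len(src[1]), off_in[2] + seq_len(src[2])]
  slab_slice(out, vol$spacing[1:2], level, subject = vol$subject)
}

#' Per-level grayscale preprocessing
#'
#' `preprocess_l1` applies the bone window [-1024, 500] producing a
#' single-channel [0,1] image; `preprocess_l3` stacks the full-contrast
#' [-1024, 2048], adipose [-190, -30] and muscle [40, 100] windows as three
#' channels.
#'
#' @param slice a [slab_slice()] with the matching level tag.
#' @param window,windows HU window(s); the defaults are the standard
#'   clinical settings.
#' @return H x W x C array in [0, 1].
#' @export
preprocess_l1 <- function(slice, window = c(-1024, 500)) {
  stopifnot(inherits(slice, "slab_slice"))
  if (slice$level != "L1") stop("preprocess_l1 applied to ", slice$level, " slice")
  window_channels(slice$hu, list(window))
}

#' @rdname preprocess_l1
#' @export
preprocess_l3 <- function(slice,
                          windows = list(c(-1024, 2048), c(-190, -30), c(40, 100))) {
  stopifnot(inherits(slice, "slab_slice"))
  if (slice$level != "L3") stop("preprocess_l3 applied to ", slice$level, " slice")
  window_channels(slice$hu, windows)
}

#' Construct a label mask
#'
#' @param labels 2D integer matrix of 0-based class labels.
#' @param level "L1" or "L3" (fixes the class vocabulary).
#' @param classes class vocabulary; defaults to [level_classes()].
#' @return a `label_mask`.
#' @export
label_mask <- function(labels, level, classes = level_classes(level)) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  if (any(labels < 0 | labels >= length(classes)))
    stop("labels outside the class vocabulary of level ", level)
  structure(list(labels = labels, level = level, classes = classes),
            class = "label_mask")
}

#' Predict a label mask from a preprocessed slice image
#'
#' Argmax over per-pixel class probabilities; exact ties break toward the
#' lower class index.
#'
#' @param model a trained `bodycomp_cnn` segmentation model.
#' @param image preprocessed H x W x C array matching the model's level.
#' @return a [label_mask()].
#' @export
predict_mask <- function(model, image) {
  stopifnot(inherits(model, "bodycomp_cnn"))
  if (!identical(model$manifest$task, "segmentation"))
    stop("model is not a segmentation model")
  p <- predict(model, image)
  lab <- apply(p, c(1, 2), which.max) - 1L   # which.max takes the first maximum
  label_mask(lab, level = model$manifest$level,
             classes = model$manifest$classes)
}

#' Modal (majority-vote) smoothing of a label mask
#'
#' Each pixel is reassigned to the most frequent class of its 3x3
#' neighbourhood; ties keep the current label. One iteration removes
#' isolated single-pixel protrusions at class boundaries while leaving
#' regions thicker than two pixels intact. This is the optional
#' post-processing step of the pipeline: off in the clinical default
#' configuration, enabled at phantom scale where single-pixel boundary
#' errors are proportionally large (see the package vignette).
#'
#' @param mask a [label_mask()].
#' @param iterations number of smoothing passes (0 returns the mask as is).
#' @return a [label_mask()].
#' @export
smooth_mask <- function(mask, iterations = 1) {
  stopifnot(inherits(mask, "label_mask"))
  labels <- mask$labels
  n_classes <- length(mask$classes)
  H <- nrow(labels); W <- ncol(labels)
  for (it in seq_len(iterations)) {
    counts <- array(0L, c(H, W, n_classes))
    padded <- matrix(-1L, H + 2, W + 2)
    padded[2:(H + 1), 2:(W + 1)] <- labels
    for (c in 0:(n_classes - 1))
      for (di in -1:1) for (dj in -1:1)
        counts[, , c + 1] <- counts[, , c + 1] +
          (padded[2:(H + 1) + di, 2:(W + 1) + dj] == c)
    bestc <- matrix(0L, H, W)
    bestn <- counts[, , 1]
    for (c in 1:(n_classes - 1)) {
      upd <- counts[, , c + 1] > bestn
      bestc[upd] <- c
      bestn[upd] <- counts[, , c + 1][upd]
    }
    idx <- cbind(rep(seq_len(H), W), rep(seq_len(W), each = H),
                 as.vector(labels) + 1L)
    orig_n <- matrix(counts[idx], H, W)
    new <- ifelse(orig_n == bestn, labels, bestc)
    storage.mode(new) <- "integer"
    labels <- new
  }
  label_mask(labels, mask$level, mask$classes)
}

#' Dice similarity coefficient for one class
#'
#' `2 |P n T| / (|P| + |T|)` over the binary masks of `class`; when both
#' masks are empty the score is defined as 1 (perfect agreement on absence).
#'
#' @param pred,truth [label_mask()] objects of equal shape, or plain logical
#'   matrices.
#' @param class class name (or 0-based label integer) scored against the mask
#'   vocabulary; ignored for logical-matrix input.
#' @return Dice score in [0, 1].
#' @export
vdsc <- function(pred, truth, class = NULL) {
  as_bin <- function(m) {
    if (is.logical(m)) return(m)
    stopifnot(inherits(m, "label_mask"))
    if (is.character(class)) {
      if (!class %in% m$classes) stop("unknown class: ", class)
      m$labels == (match(class, m$classes) - 1L)
    } else {
      m$labels == as.integer(class)
    }
  }
  p <- as_bin(pred); t <- as_bin(truth)
  stopifnot(all(dim(p) == dim(t)))
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1)
  2 * sum(p & t) / denom
}
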