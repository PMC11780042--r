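# Localization of the axial slices intersecting L1 and L3: sagittal
# projection, HU multi-window channel composition, resize to the model grid,
# Gaussian heatmap targets, and two-peak extraction from predictions.
#
# Projection images are matrices with rows spanning anterior-posterior and
# columns spanning inferior-superior (the long axis of a thoraco-abdominal
# scan); pixel coordinates (u, v) are 0-based (u = AP row, v = SI column).

#' Sagittal projection of a CT volume
#'
#' Reduces the right-left axis by a maximum-intensity (default) or mean
#' projection restricted to a central sagittal slab, which suppresses ribs
#' and arms while keeping the vertebral column conspicuous.
#'
#' @param vol a canonical, isotropic [ct_volume()].
#' @param mode "mip" (maximum-intensity) or "mean".
#' @param slab_frac fraction of the right-left extent, centred, used for the
#'   projection (default 0.5).
#' @return list with `img` (AP x SI HU matrix) and `spacing` (mm per pixel
#'   along AP and SI).
#' @export
sagittal_project <- function(vol, mode = c("mip", "mean"), slab_frac = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$voxels)
  if (d[1] < 2) stop("fewer than 2 voxels along the right-left axis")
  half <- max(1L, round(d[1] * slab_frac / 2))
  ctr <- (d[1] + 1) / 2
  sel <- max(1L, floor(ctr - half)):min(d[1], ceiling(ctr + half))
  slab <- vol$voxels[sel, , , drop = FALSE]
  img <- if (mode == "mip") apply(slab, c(2, 3), max) else apply(slab, c(2, 3), mean)
  list(img = img, spacing = vol$spacing[2:3])
}

#' Apply HU windows as [0,1] channels
#'
#' Each window (lo, hi) produces one channel `clip((HU - lo)/(hi - lo), 0, 1)`;
#' channels are stacked in the given order.
#'
#' @param img 2D HU matrix.
#' @param windows list of numeric length-2 vectors c(lo, hi), lo < hi.
#' @return array H x W x length(windows) with values in [0, 1].
#' @export
window_channels <- function(img, windows) {
  if (length(windows) == 0) stop("empty window list")
  out <- array(0, c(dim(img), length(windows)))
  for (c in seq_along(windows)) {
    w <- windows[[c]]
    if (w[1] >= w[2]) stop("window must have lo < hi: ", paste(w, collapse = ", "))
    out[, , c] <- pmin(pmax((img - w[1]) / (w[2] - w[1]), 0), 1)
  }
  out
}

# Gaussian pre-blur before downscaling (anti-aliasing), then bilinear resize.
resize2d <- function(m, shape) {
  scale <- dim(m) / shape   # input pixels per output pixel
  if (any(scale > 1)) {
    sig <- pmax((scale - 1) / 2, 0)
    if (max(sig) > 0.01)
      m <- EBImage::gblur(m, sigma = max(sig))
  }
  EBImage::resize(m, w = shape[1], h = shape[2], filter = "bilinear")
}

#' Resize a multi-channel projection onto the model grid
#'
#' Anti-aliased bilinear resize of each channel to `shape` (default 128 x 256,
#' AP x SI), composing the geometry so that any grid pixel maps back to a
#' physical (AP, SI) position in mm.
#'
#' @param img H x W x C array in [0, 1] (or an H x W matrix).
#' @param spacing mm per input pixel along (AP, SI).
#' @param shape output grid, default c(128, 256).
#' @param subject subject identifier.
#' @return a `projection_record`: `channels` (shape x C, clipped to [0, 1]),
#'   `transform` (pixel-to-mm scale per axis) and `subject`.
#' @export
resize_to_grid <- function(img, spacing, shape = c(128L, 256L),
                           subject = "anonymous") {
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  d <- dim(img)
  if (d[1] < 2 || d[2] < 2) stop("input image must be at least 2x2")
  channels <- array(0, c(shape, d[3]))
  for (c in seq_len(d[3]))
    channels[, , c] <- pmin(pmax(resize2d(img[, , c], shape), 0), 1)
  structure(list(channels = channels,
                 transform = list(scale = d[1:2] / shape,  # input px per grid px
                                  spacing = spacing,
                                  input_dim = d[1:2], shape = as.integer(shape)),
                 subject = subject),
            class = "projection_record")
}

#' Map projection-grid pixels to physical mm positions and back
#'
#' Coordinates are 0-based; pixel centres map through the resize scale onto
#' input-projection pixel centres, then to mm via the projection spacing.
#'
#' @param record a `projection_record`.
#' @param uv numeric length-2 pixel coordinate (u = AP, v = SI) or a 2-column
#'   matrix of such coordinates.
#' @param mm numeric length-2 (AP, SI) mm position or a 2-column matrix.
#' @return the mapped coordinates (same shape as the input).
#' @export
px_to_mm <- function(record, uv) {
  tr <- record$transform
  uv <- rbind(uv)
  sweep(sweep(sweep(uv + 0.5, 2, tr$scale, `*`), 2, 0.5, `-`), 2, tr$spacing, `*`)
}

#' @rdname px_to_mm
#' @export
mm_to_px <- function(record, mm) {
  tr <- record$transform
  mm <- rbind(mm)
  sweep(sweep(sweep(mm, 2, tr$spacing, `/`), 2, 0.5, `+`), 2, tr$scale, `/`) - 0.5
}

#' Gaussian heatmap target for two vertebral centres
#'
#' Each centre is rendered as an isotropic Gaussian blob (the closed form of
#' a Gaussian-filtered delta image) and blobs are composed by element-wise
#' maximum, the standard convention in landmark-heatmap generation: it keeps
#' every centre an exact argmax of its blob at any separation, and for
#' centres at least 3 sigma apart it differs from the summed (filtered)
#' image by less than exp(-9/2). The map is normalized so the global maximum
#' is 1, per the convention that centre pixels carry value 1.
#'
#' @param centers 2 x 2 matrix of 0-based pixel coordinates, one row per
#'   centre (u = AP, v = SI); a single centre may be given as a length-2
#'   vector.
#' @param shape heatmap dimensions, default c(128, 256).
#' @param sigma Gaussian standard deviation in pixels (default 15).
#' @return a `heatmap` object: `values` (non-negative matrix, max 1) and
#'   `sigma`.
#' @export
make_target <- function(centers, shape = c(128L, 256L), sigma = 15) {
  stopifnot(sigma > 0)
  centers <- rbind(centers)
  if (any(centers[, 1] < 0 | centers[, 1] > shape[1] - 1 |
          centers[, 2] < 0 | centers[, 2] > shape[2] - 1))
    stop("centres must lie inside the image")
  if (nrow(centers) == 2 &&
      sqrt(sum((centers[1, ] - centers[2, ])^2)) < 1)
    stop("degenerate target: centres closer than 1 pixel")
  u <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  v <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
  vals <- matrix(0, shape[1], shape[2])
  for (r in seq_len(nrow(centers)))
    vals <- pmax(vals,
                 exp(-((u - centers[r, 1])^2 + (v - centers[r, 2])^2) /
                       (2 * sigma^2)))
  vals <- vals / max(vals)
  structure(list(values = vals, sigma = sigma), class = "heatmap")
}

# All strict-or-equal local maxima of a matrix over the 8-neighbourhood.
local_maxima <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(-Inf, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  ok <- matrix(TRUE, H, W)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ok & (m >= p[2:(H + 1) + di, 2:(W + 1) + dj])
  }
  which(ok, arr.ind = TRUE)
}

#' Extract the L1 and L3 centres from a predicted heatmap
#'
#' Finds local maxima above an intensity floor, enforces a minimum peak
#' separation, keeps the two most intense peaks and assigns the superior one
#' to L1 and the inferior one to L3 (anatomical order, not intensity order).
#' Pixel positions are mapped through the projection geometry to mm and to
#' the nearest axial slice of `vol`.
#'
#' @param hm a `heatmap` or a plain non-negative matrix (model prediction).
#' @param record the `projection_record` the heatmap corresponds to.
#' @param vol the isotropic [ct_volume()] the projection came from.
#' @param sigma peak scale in pixels; minimum peak separation is `2 * sigma`.
#' @param floor_frac intensity floor as a fraction of the global maximum.
#' @return a `center_prediction`: per level a 0-based pixel `px`, the SI
#'   position `mm`, and the 0-based axial `slice`; plus `peak_intensities`.
#' @export
extract_centers <- function(hm, record, vol, sigma = 15, floor_frac = 0.1) {
  vals <- if (inherits(hm, "heatmap")) hm$values else hm
  if (inherits(hm, "heatmap")) sigma <- hm$sigma
  if (!all(dim(vals) == dim(record$channels)[1:2]))
    stop("heatmap shape does not match projection record")
  mx <- max(vals)
  if (!is.finite(mx) || mx <= 0)
    stop_bodycomp("no peaks found in heatmap", "bodycomp_detection_failure")
  cand <- local_maxima(vals)
  cand <- cand[vals[cand] >= floor_frac * mx, , drop = FALSE]
  # order by intensity, ties broken by superior (larger SI column) first
  ord <- order(-vals[cand], -cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- matrix(numeric(0), 0, 2)
  for (r in seq_len(nrow(cand))) {
    if (nrow(keep) == 2) break
    if (nrow(keep) == 0 ||
        all(sqrt(rowSums(sweep(keep, 2, cand[r, ])^2)) >= 2 * sigma))
      keep <- rbind(keep, cand[r, ])
  }
  if (nrow(keep) < 2)
    stop_bodycomp("fewer than two peaks found in heatmap",
                  "bodycomp_detection_failure")
  px <- keep - 1          # to 0-based (u, v)
  ints <- vals[keep]
  sup <- which.max(px[, 2])
  mk <- function(i) {
    mm <- px_to_mm(record, px[i, ])
    k <- round(mm[2] / vol$spacing[3])
    k <- min(max(k, 0), dim(vol$voxels)[3] - 1)
    list(px = unname(px[i, ]), mm = unname(mm[2]), slice = as.integer(k))
  }
  structure(list(l1 = mk(sup), l3 = mk(3 - sup),
                 peak_intensities = unname(c(ints[sup], ints[3 - sup])),
                 subject = record$subject),
            class = "center_prediction")
}

#' Localization error of a centre prediction against ground truth
#'
#' Distances are measured along the superior-inferior axis (the quantity that
#' determines slice selection), in mm and in axial slices.
#'
#' @param pred a `center_prediction`.
#' @param truth an [annotation()] with 0-based voxel centres.
#' @param vol the [ct_volume()] both refer to.
#' @return named numeric: `l1_mm`, `l3_mm`, `l1_slices`, `l3_slices`.
#' @export
localization_error <- function(pred, truth, vol) {
  tz <- c(l1 = truth$l1_center[3], l3 = truth$l3_center[3]) * vol$spacing[3]
  c(l1_mm = abs(pred$l1$mm - tz[["l1"]]),
    l3_mm = abs(pred$l3$mm - tz[["l3"]]),
    l1_slices = abs(pred$l1$slice - truth$l1_center[3]),
    l3_slices = abs(pred$l3$slice - truth$l3_center[3]))
}
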