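# Synthetic thoraco-abdominal CT phantoms with exact ground truth.
#
# Each phantom is an elliptical torso containing, from outside in: a
# subcutaneous fat ring (SAT), a muscle wall (SMA at L3), a soft-tissue
# interior with visceral fat blobs (VAT), and a lumbar vertebral column of
# cylindrical bodies (trabecular core + cortical shell, separated by
# intervertebral discs). Tissue HU values are sampled from tissue-typical
# normal distributions consistent with the clinical window settings, plus
# global acquisition noise. The most superior vertebra of the column is L1
# and the third is L3; the column top varies between subjects so the
# localization task is well-posed.

#' Phantom specification
#'
#' All geometric parameters are in voxels of the phantom grid (default 2 mm
#' isotropic, 96 x 96 x 120, so CPU training fits in minutes; pass a larger
#' shape/spacing for full-resolution 512-grid slices).
#'
#' @param shape volume dimensions (right-left, anterior-posterior,
#'   inferior-superior).
#' @param spacing voxel spacing in mm.
#' @param body_radii torso half-axes (RL, AP) in voxels.
#' @param sat_thickness subcutaneous fat ring thickness in voxels.
#' @param muscle_thickness muscle wall thickness in voxels.
#' @param spine_offset_frac posterior offset of the spine centre as a
#'   fraction of the inner-cavity AP radius.
#' @param vert_core_radius trabecular core radius in voxels.
#' @param vert_shell_thickness cortical shell thickness in voxels.
#' @param n_vertebrae,vert_height,gap column structure in voxels.
#' @param column_top 0-based slice index of the top of the first (L1)
#'   vertebra.
#' @param n_vat_blobs,vat_radius_range visceral fat blob count and radius
#'   range in voxels.
#' @param hu list of tissue HU distributions, each c(mean, sd): `trab`,
#'   `cortical`, `fat` (bounded to [-190, -30]), `muscle`, `organ`, `disc`;
#'   plus scalar `air`. Fat and muscle means must respect the clinical
#'   adipose [-190, -30] and muscle [40, 100] windows.
#' @param noise_sd global additive Gaussian noise sd in HU.
#' @param seed integer seed; fully determines the phantom.
#' @param subject subject identifier.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 120L), spacing = c(2, 2, 2),
                         body_radii = c(35, 30), sat_thickness = 5,
                         muscle_thickness = 3, spine_offset_frac = 0.45,
                         vert_core_radius = 5, vert_shell_thickness = 1.5,
                         n_vertebrae = 5L, vert_height = 12L, gap = 3L,
                         column_top = 104L, n_vat_blobs = 8L,
                         vat_radius_range = c(2.5, 6),
                         hu = list(trab = c(160, 30), cortical = c(1200, 50),
                                   fat = c(-100, 20), muscle = c(55, 12),
                                   organ = c(20, 10), disc = c(80, 10),
                                   air = -1024),
                         noise_sd = 10, seed = 1, subject = "phantom") {
  if (hu$fat[1] < -190 || hu$fat[1] > -30)
    stop("fat HU mean must lie inside the adipose window [-190, -30]")
  if (hu$muscle[1] < 40 || hu$muscle[1] > 100)
    stop("muscle HU mean must lie inside the muscle window [40, 100]")
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               body_radii = body_radii, sat_thickness = sat_thickness,
               muscle_thickness = muscle_thickness,
               spine_offset_frac = spine_offset_frac,
               vert_core_radius = vert_core_radius,
               vert_shell_thickness = vert_shell_thickness,
               n_vertebrae = as.integer(n_vertebrae),
               vert_height = as.integer(vert_height), gap = as.integer(gap),
               column_top = as.integer(column_top),
               n_vat_blobs = as.integer(n_vat_blobs),
               vat_radius_range = vat_radius_range, hu = hu,
               noise_sd = noise_sd, seed = as.integer(seed), subject = subject)
  class(spec) <- "phantom_spec"
  spec
}

in_ellipse <- function(X, Y, cx, cy, rx, ry) {
  ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1
}

#' Generate one phantom volume with its ground-truth annotation
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [ct_volume()]) and `annotation` (an
#'   [annotation()] carrying exact L1/L3 centres and per-class label masks at
#'   those slices).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  rx <- spec$body_radii[1]; ry <- spec$body_radii[2]
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
  if (cx - rx < 1 || cy - ry < 1)
    stop("body ellipse does not fit the volume cross-section")
  hv <- spec$vert_height; gap <- spec$gap
  col_bottom <- spec$column_top - spec$n_vertebrae * hv -
    (spec$n_vertebrae - 1) * gap
  if (col_bottom < 0 || spec$column_top > d[3] - 1)
    stop("vertebral column does not fit the volume")

  ri <- c(rx, ry) - spec$sat_thickness               # inner SAT boundary
  rm_ <- ri - spec$muscle_thickness                  # inner muscle boundary
  if (any(rm_ < spec$vert_core_radius + spec$vert_shell_thickness + 3))
    stop("cavity too small for the vertebral column")
  vy <- cy - spec$spine_offset_frac * rm_[2]         # spine centre (posterior)
  rv <- spec$vert_core_radius
  rs <- rv + spec$vert_shell_thickness

  X <- matrix(0:(d[1] - 1), d[1], d[2])
  Y <- matrix(0:(d[2] - 1), d[1], d[2], byrow = TRUE)
  body <- in_ellipse(X, Y, cx, cy, rx, ry)
  cavity <- in_ellipse(X, Y, cx, cy, ri[1], ri[2])
  interior <- in_ellipse(X, Y, cx, cy, rm_[1], rm_[2])
  sat2d <- body & !cavity
  mus2d <- cavity & !interior
  core2d <- (X - cx)^2 + (Y - vy)^2 <= rv^2
  shell2d <- ((X - cx)^2 + (Y - vy)^2 <= rs^2) & !core2d

  with_seed(spec$seed, {
    # visceral fat blobs inside the cavity, clear of the vertebral column
    nb <- spec$n_vat_blobs
    vat2d <- matrix(FALSE, d[1], d[2])
    tries <- 0
    placed <- 0
    while (placed < nb && tries < 50 * nb) {
      tries <- tries + 1
      br <- runif(1, spec$vat_radius_range[1], spec$vat_radius_range[2])
      bx <- cx + runif(1, -1, 1) * (rm_[1] - br - 1)
      by <- cy + runif(1, -1, 1) * (rm_[2] - br - 1)
      if (!in_ellipse(bx, by, cx, cy, rm_[1] - br, rm_[2] - br)) next
      if ((bx - cx)^2 + (by - vy)^2 <= (rs + br + 2)^2) next
      vat2d <- vat2d | ((X - bx)^2 + (Y - by)^2 <= br^2)
      placed <- placed + 1
    }
    vat2d <- vat2d & interior

    # label codes: 0 air, 1 sat, 2 muscle, 3 organ, 4 vat, 5 trab, 6 cortical, 7 disc
    base2d <- matrix(0L, d[1], d[2])
    base2d[sat2d] <- 1L
    base2d[mus2d] <- 2L
    base2d[interior] <- 3L
    base2d[vat2d] <- 4L

    lab <- array(rep(base2d, d[3]), d)
    spine2d <- base2d
    spine2d[shell2d] <- 6L
    spine2d[core2d] <- 5L
    disc2d <- base2d
    disc2d[shell2d | core2d] <- 7L
    centers_k <- integer(spec$n_vertebrae)
    for (v in seq_len(spec$n_vertebrae)) {
      top <- spec$column_top - (v - 1) * (hv + gap)
      ks <- (top - hv + 1):top
      lab[, , ks + 1L] <- array(rep(spine2d, hv), c(d[1:2], hv))
      centers_k[v] <- as.integer(round(top - hv / 2))
      if (v < spec$n_vertebrae) {
        gs <- (top - hv - gap + 1):(top - hv)
        lab[, , gs + 1L] <- array(rep(disc2d, gap), c(d[1:2], gap))
      }
    }

    vox <- numeric(length(lab))
    vox[lab == 0L] <- spec$hu$air
    draw <- function(code, mu, sd) {
      idx <- which(lab == code)
      if (length(idx)) vox[idx] <<- rnorm(length(idx), mu, sd)
    }
    draw(1L, spec$hu$fat[1], spec$hu$fat[2])
    draw(4L, spec$hu$fat[1], spec$hu$fat[2])
    vox[lab == 1L | lab == 4L] <- pmin(pmax(vox[lab == 1L | lab == 4L], -190), -30)
    draw(2L, spec$hu$muscle[1], spec$hu$muscle[2])
    draw(3L, spec$hu$organ[1], spec$hu$organ[2])
    draw(5L, spec$hu$trab[1], spec$hu$trab[2])
    draw(6L, spec$hu$cortical[1], spec$hu$cortical[2])
    draw(7L, spec$hu$disc[1], spec$hu$disc[2])
    vox <- vox + rnorm(length(vox), 0, spec$noise_sd)
    dim(vox) <- d

    vol <- ct_volume(vox, spec$spacing, subject = spec$subject)

    k1 <- centers_k[1]; k3 <- centers_k[3]
    l1_lab <- matrix(0L, d[1], d[2])
    l1_lab[core2d] <- 1L; l1_lab[shell2d] <- 2L
    l3_lab <- matrix(0L, d[1], d[2])
    l3_lab[mus2d] <- 1L; l3_lab[vat2d] <- 2L; l3_lab[sat2d] <- 3L
    ann <- annotation(l1_center = c(round(cx), round(vy), k1),
                      l3_center = c(round(cx), round(vy), k3),
                      l1_mask = label_mask(l1_lab, "L1"),
                      l3_mask = label_mask(l3_lab, "L3"),
                      subject = spec$subject)
    list(volume = vol, annotation = ann, spec = spec)
  })
}

#' Generate a phantom dataset with varied anatomy
#'
#' Body size, fat-ring thickness, muscle-wall thickness, visceral fat and the
#' position of the vertebral column are sampled per subject from realistic
#' ranges; the overall `seed` fixes every draw, so datasets are bitwise
#' reproducible.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param shape,spacing grid of every phantom (see [phantom_spec()]).
#' @return list of `n` elements, each a list with `volume`, `annotation` and
#'   `spec`.
#' @export
generate_dataset <- function(n, seed = 1, shape = c(96L, 96L, 120L),
                             spacing = c(2, 2, 2)) {
  stopifnot(n >= 1)
  params <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      list(body_radii = c(runif(1, 30, 40), runif(1, 26, 34)),
           sat_thickness = runif(1, 3.5, 7),
           muscle_thickness = runif(1, 2.5, 4.5),
           column_top = sample(95:112, 1),
           n_vat_blobs = sample(5:10, 1),
           spine_offset_frac = runif(1, 0.4, 0.55),
           vert_core_radius = runif(1, 4.5, 6),
           seed = sample.int(2^31 - 2, 1))
    })
  })
  lapply(seq_len(n), function(i) {
    p <- params[[i]]
    generate_phantom(phantom_spec(
      shape = shape, spacing = spacing,
      body_radii = p$body_radii, sat_thickness = p$sat_thickness,
      muscle_thickness = p$muscle_thickness, column_top = p$column_top,
      n_vat_blobs = p$n_vat_blobs, spine_offset_frac = p$spine_offset_frac,
      vert_core_radius = p$vert_core_radius,
      seed = p$seed, subject = sprintf("phantom_%03d", i)))
  })
}
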