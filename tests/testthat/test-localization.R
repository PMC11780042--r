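test_that("sagittal projection reduces the right-left axis correctly", {
  # constant volume -> constant projection
  v <- ct_volume(array(100, c(8, 10, 12)), c(1, 1, 1))
  p <- sagittal_project(v)
  expect_equal(dim(p$img), c(10L, 12L))
  expect_true(all(p$img == 100))

  # single bright voxel inside the central slab -> one bright pixel at its
  # (AP, SI) location under max projection
  a <- array(-1000, c(8, 10, 12))
  a[4, 7, 9] <- 2000
  v2 <- ct_volume(a, c(1, 1, 1))
  p2 <- sagittal_project(v2, mode = "mip")
  expect_equal(which(p2$img == 2000, arr.ind = TRUE)[1, ], c(row = 7, col = 9))

  # general case agrees with a per-pixel loop oracle over the reduced axis
  set.seed(21)
  a3 <- array(rnorm(8 * 10 * 12, 0, 300), c(8, 10, 12))
  v3 <- suppressWarnings(ct_volume(a3, c(1, 1, 1)))
  p3 <- sagittal_project(v3, slab_frac = 0.5)
  half <- max(1, round(8 * 0.5 / 2))
  sel <- max(1, floor(4.5 - half)):min(8, ceiling(4.5 + half))
  oracle <- matrix(0, 10, 12)
  for (j in 1:10) for (k in 1:12) oracle[j, k] <- max(a3[sel, j, k])
  expect_equal(p3$img, oracle)

  expect_error(sagittal_project(ct_volume(array(0, c(1, 4, 4)), c(1, 1, 1))),
               "fewer than 2")
})

test_that("window_channels matches the affine clip form and is monotone", {
  img <- matrix(c(-1024, -262, 0, 500, 1000, 3000), 2, 3)
  ch <- window_channels(img, list(c(-1024, 500), c(1000, 2000)))
  expect_equal(ch[, , 1][img == -1024], 0)
  expect_equal(ch[, , 1][img == 500], 1)
  expect_equal(ch[, , 1][img == -262], 0.5)
  expect_equal(ch[, , 1][img == 3000], 1)   # clipped
  expect_equal(ch[, , 2][img == 3000], 1)
  expect_equal(ch[, , 2][img == 0], 0)
  # monotone non-decreasing in HU per channel
  hu <- seq(-1200, 3000, length.out = 500)
  chm <- window_channels(matrix(hu, 1), list(c(400, 500)))
  expect_true(all(diff(chm[1, , 1]) >= 0))
  expect_error(window_channels(img, list()), "empty")
  expect_error(window_channels(img, list(c(5, 5))), "lo < hi")
})

test_that("resize_to_grid preserves constants, range and geometry", {
  const <- array(0.4, c(40, 60, 3))
  rec <- resize_to_grid(const, spacing = c(2, 2), shape = c(32, 64))
  expect_equal(dim(rec$channels), c(32L, 64L, 3L))
  expect_true(all(abs(rec$channels - 0.4) < 1e-6))

  # identity shape -> unchanged within tolerance
  set.seed(3)
  img <- array(runif(128 * 256), c(128, 256, 1))
  rec2 <- resize_to_grid(img, spacing = c(1, 1), shape = c(128, 256))
  expect_lt(max(abs(rec2$channels[, , 1] - img[, , 1])), 1e-6)

  # transform round-trips within 0.5 pixel and maps geometry consistently
  rec3 <- resize_to_grid(array(0.5, c(96, 120, 1)), spacing = c(2, 2),
                         shape = c(64, 128))
  uv <- rbind(c(10.2, 90.7), c(0, 0), c(63, 127))
  back <- mm_to_px(rec3, px_to_mm(rec3, uv))
  expect_lt(max(abs(back - uv)), 0.5)
  # a known voxel: AP index 30, SI index 60 at 2 mm -> (60, 120) mm
  px <- mm_to_px(rec3, c(60, 120))
  expect_equal(as.numeric(px_to_mm(rec3, px)), c(60, 120), tolerance = 1e-9)
})

test_that("make_target renders exact-argmax Gaussian blobs", {
  # single centre: argmax at centre, max exactly 1
  hm1 <- make_target(c(40, 60), shape = c(128, 256), sigma = 15)
  expect_equal(max(hm1$values), 1)
  expect_equal(which(hm1$values == 1, arr.ind = TRUE)[1, ],
               c(row = 41, col = 61))
  # values vanish outside 4 sigma of every centre
  u <- row(hm1$values) - 1; v <- col(hm1$values) - 1
  far <- sqrt((u - 40)^2 + (v - 60)^2) > 4 * 15
  expect_lt(max(hm1$values[far]), 1e-3)

  # two centres 100 px apart: local maxima at both centres, and agreement
  # with the direct Gaussian-kernel summation oracle wherever one kernel
  # dominates (within 1 sigma of a centre the other kernel is ~1e-7)
  cs <- rbind(c(60, 70), c(60, 170))
  hm2 <- make_target(cs, shape = c(128, 256), sigma = 15)
  oracle <- exp(-((u - 60)^2 + (v - 70)^2) / 450) +
    exp(-((u - 60)^2 + (v - 170)^2) / 450)
  oracle <- oracle / max(oracle)
  near <- pmin(sqrt((u - 60)^2 + (v - 70)^2),
               sqrt((u - 60)^2 + (v - 170)^2)) <= 15
  expect_lt(max(abs(hm2$values - oracle)[near]), 1e-6)
  expect_equal(hm2$values[61, 71], 1)
  expect_equal(hm2$values[61, 171], 1)
  lm2 <- bodycomp:::local_maxima(hm2$values)
  expect_true(any(lm2[, 1] == 61 & lm2[, 2] == 71))
  expect_true(any(lm2[, 1] == 61 & lm2[, 2] == 171))

  # near-delta limit: mass concentrated within 2 px of the centres
  hm3 <- make_target(rbind(c(10, 10), c(30, 40)), shape = c(64, 64), sigma = 0.5)
  u3 <- row(hm3$values) - 1; v3 <- col(hm3$values) - 1
  near <- pmin(sqrt((u3 - 10)^2 + (v3 - 10)^2),
               sqrt((u3 - 30)^2 + (v3 - 40)^2)) <= 2
  expect_gt(sum(hm3$values[near]), 0.999 * sum(hm3$values))

  expect_error(make_target(rbind(c(5, 5), c(5.2, 5.3)), c(64, 64), 3),
               "degenerate")
  expect_error(make_target(c(-3, 5), c(64, 64), 3), "inside")
})

test_that("extract_centers recovers constructed centres and ranks peaks", {
  rec <- identity_record(c(128L, 256L))
  vol <- flat_volume(256L)
  cs <- rbind(c(30, 200), c(90, 80))   # first is superior (L1)
  hm <- make_target(cs, shape = c(128, 256), sigma = 15)
  pred <- extract_centers(hm, rec, vol)
  expect_equal(pred$l1$px, c(30, 200))
  expect_equal(pred$l3$px, c(90, 80))
  expect_equal(pred$l1$slice, 200L)
  expect_equal(pred$l3$slice, 80L)

  # three blobs 1.0 / 0.9 / 0.2: the two strongest are returned, matching a
  # brute-force ranking of all local maxima
  mk_blob <- function(u0, v0, amp, s = 6) {
    u <- matrix(0:127, 128, 256); v <- matrix(0:255, 128, 256, byrow = TRUE)
    amp * exp(-((u - u0)^2 + (v - v0)^2) / (2 * s^2))
  }
  m <- pmax(mk_blob(20, 40, 1.0), mk_blob(64, 128, 0.9), mk_blob(100, 220, 0.2))
  pred2 <- extract_centers(m, rec, vol, sigma = 6)
  expect_equal(sort(pred2$peak_intensities, decreasing = TRUE),
               c(1.0, 0.9), tolerance = 1e-6)
  # L1 is assigned by anatomy (superior, v = 128), not by intensity
  expect_equal(pred2$l1$px, c(64, 128))
  expect_equal(pred2$l3$px, c(20, 40))

  # degenerate inputs fail loudly with the detection-failure class
  expect_error(extract_centers(matrix(0, 128, 256), rec, vol),
               class = "bodycomp_detection_failure")
  one <- mk_blob(64, 128, 1)
  expect_error(extract_centers(one, rec, vol, sigma = 6),
               class = "bodycomp_detection_failure")
})

test_that("localization_error measures SI distance in mm and slices", {
  vol <- ct_volume(array(0, c(4, 4, 40)), c(1, 1, 3))
  ann <- annotation(c(2, 2, 30), c(2, 2, 14))
  pred <- structure(list(
    l1 = list(px = c(0, 0), mm = 30 * 3, slice = 30L),
    l3 = list(px = c(0, 0), mm = 14 * 3, slice = 14L)), class = "center_prediction")
  expect_equal(unname(localization_error(pred, ann, vol)), c(0, 0, 0, 0))
  # a 2-slice offset at 3 mm spacing is 6 mm
  pred$l3$mm <- 16 * 3; pred$l3$slice <- 16L
  err <- localization_error(pred, ann, vol)
  expect_equal(unname(err["l3_mm"]), 6)
  expect_equal(unname(err["l3_slices"]), 2)
})

test_that("heatmap round-trip is exact for random separated centre pairs", {
  # property over 100 seeded pairs >= 3 sigma apart on the 128 x 256 grid
  rec <- identity_record(c(128L, 256L))
  vol <- flat_volume(256L)
  sigma <- 15
  set.seed(2024)
  done <- 0
  while (done < 100) {
    c1 <- c(sample(0:127, 1), sample(0:255, 1))
    c2 <- c(sample(0:127, 1), sample(0:255, 1))
    if (sqrt(sum((c1 - c2)^2)) < 3 * sigma) next
    done <- done + 1
    hm <- make_target(rbind(c1, c2), shape = c(128, 256), sigma = sigma)
    pred <- extract_centers(hm, rec, vol)
    sup <- if (c1[2] >= c2[2]) c1 else c2
    inf <- if (c1[2] >= c2[2]) c2 else c1
    expect_identical(as.numeric(pred$l1$px), as.numeric(sup))
    expect_identical(as.numeric(pred$l3$px), as.numeric(inf))
  }
})
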