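test_that("region_area converts pixel counts to cm^2", {
  lab <- matrix(0L, 20, 20)
  lab[1:10, 1:10] <- 1L                     # 100 pixels
  m <- label_mask(lab, "L1")
  expect_equal(region_area(m, "trabecular", c(1, 1)), 1)
  expect_equal(region_area(m, "cortical", c(1, 1)), 0)
  # 173 pixels at 0.76 mm: 173 * 0.5776 / 100
  lab2 <- matrix(0L, 20, 20); lab2[seq_len(173)] <- 1L
  m2 <- label_mask(lab2, "L1")
  expect_equal(region_area(m2, "trabecular", c(0.76, 0.76)), 173 * 0.76^2 / 100)
  # linear in count, quadratic in isotropic spacing
  expect_equal(region_area(m, "trabecular", c(2, 2)),
               4 * region_area(m, "trabecular", c(1, 1)))
})

test_that("density stats use original HU and the population sd convention", {
  lab <- matrix(0L, 4, 4); lab[1:2, 1] <- 1L
  m <- label_mask(lab, "L1")
  hu <- matrix(0, 4, 4); hu[1, 1] <- 100; hu[2, 1] <- 200
  st <- region_density_stats(m, "trabecular", hu)
  expect_equal(unname(st["mean"]), 150)
  expect_equal(unname(st["sd"]), 50)        # population, not sample (70.71)
  # constant region
  hu2 <- matrix(150, 4, 4)
  expect_equal(unname(region_density_stats(m, "trabecular", hu2)), c(150, 0))
  # empty region raises, not silently 0
  expect_error(region_density_stats(m, "cortical", hu),
               class = "bodycomp_undefined_statistic")
  # invariant to relabeling of other classes
  lab3 <- lab; lab3[4, 4] <- 2L
  expect_equal(region_density_stats(label_mask(lab3, "L1"), "trabecular", hu), st)
})

test_that("density stats recover an injected normal distribution", {
  set.seed(33)
  lab <- matrix(0L, 40, 40); lab[1:600] <- 1L
  hu <- matrix(0, 40, 40); hu[1:600] <- rnorm(600, 160, 30)
  st <- region_density_stats(label_mask(lab, "L1"), "trabecular", hu)
  expect_lt(abs(st["mean"] - 160) / 160, 0.05)
  expect_lt(abs(st["sd"] - 30) / 30, 0.10)
})

test_that("compute_report equals a per-pixel brute-force oracle bit-for-bit", {
  brute <- function(l1_lab, l1_hu, l3_lab, l3_hu, sp) {
    acc <- function(lab, hu, cls) {
      n <- 0; vals <- numeric(0)
      for (i in seq_len(nrow(lab))) for (j in seq_len(ncol(lab))) {
        if (lab[i, j] == cls) { n <- n + 1; vals <- c(vals, hu[i, j]) }
      }
      list(n = n, vals = vals)
    }
    tr <- acc(l1_lab, l1_hu, 1L)
    sat <- acc(l3_lab, l3_hu, 3L)
    sma <- acc(l3_lab, l3_hu, 1L)
    vat <- acc(l3_lab, l3_hu, 2L)
    mu <- mean(tr$vals)
    musat <- mean(sat$vals)
    list(bmd_avg = mu,
         bmd_sd = sqrt(mean((tr$vals - mu)^2)),
         l1_trab_area = tr$n * sp[1] * sp[2] / 100,
         l3_sat_area = sat$n * sp[1] * sp[2] / 100,
         l3_sma = sma$n * sp[1] * sp[2] / 100,
         l3_vat_area = vat$n * sp[1] * sp[2] / 100,
         l3_sat_density_sd = sqrt(mean((sat$vals - musat)^2)))
  }
  set.seed(77)
  for (rep in 1:20) {
    l1_lab <- matrix(sample(0:2, 64 * 64, TRUE, prob = c(0.9, 0.07, 0.03)), 64, 64)
    l3_lab <- matrix(sample(0:3, 64 * 64, TRUE, prob = c(0.7, 0.1, 0.1, 0.1)), 64, 64)
    storage.mode(l1_lab) <- "integer"; storage.mode(l3_lab) <- "integer"
    l1_hu <- matrix(rnorm(64 * 64, 100, 300), 64, 64)
    l3_hu <- matrix(rnorm(64 * 64, -50, 150), 64, 64)
    sp <- runif(2, 0.5, 2)
    rep_pkg <- compute_report(label_mask(l1_lab, "L1"), l1_hu,
                              label_mask(l3_lab, "L3"), l3_hu, sp)
    rep_oracle <- brute(l1_lab, l1_hu, l3_lab, l3_hu, sp)
    for (nm in names(rep_oracle))
      expect_identical(rep_pkg[[nm]], rep_oracle[[nm]])
  }
})

test_that("per-class areas partition the slice area exactly", {
  set.seed(12)
  lab <- matrix(sample(0:3, 48 * 48, TRUE), 48, 48)
  storage.mode(lab) <- "integer"
  m <- label_mask(lab, "L3")
  sp <- c(0.76, 0.76)
  total <- sum(vapply(level_classes("L3"), function(cl)
    region_area(m, cl, sp), 0))
  expect_identical(total, 48 * 48 * sp[1] * sp[2] / 100)
})

test_that("all-background masks give zero areas and undefined density", {
  l1 <- label_mask(matrix(0L, 8, 8), "L1")
  l3 <- label_mask(matrix(0L, 8, 8), "L3")
  hu <- matrix(0, 8, 8)
  expect_equal(region_area(l1, "trabecular", c(1, 1)), 0)
  expect_error(compute_report(l1, hu, l3, hu, c(1, 1)),
               class = "bodycomp_undefined_statistic")
})

test_that("report writers emit JSON and CSV with the seven index columns", {
  lab1 <- matrix(0L, 8, 8); lab1[2:3, 2:3] <- 1L
  lab3 <- matrix(0L, 8, 8); lab3[1:2, 1] <- 1L; lab3[5, 5] <- 2L; lab3[8, 8] <- 3L
  rep1 <- compute_report(label_mask(lab1, "L1"), matrix(160, 8, 8),
                         label_mask(lab3, "L3"), matrix(-100, 8, 8),
                         c(1, 1), subject = "s1")
  fj <- tempfile(fileext = ".json"); fc <- tempfile(fileext = ".csv")
  write_report(rep1, fj)
  write_report(list(rep1, rep1), fc)
  j <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(j$bmd_avg, 160)
  df <- read.csv(fc)
  expect_equal(nrow(df), 2)
  expect_true(all(c("subject", "bmd_avg", "bmd_sd", "l1_trab_area",
                    "l3_sat_area", "l3_sma", "l3_vat_area",
                    "l3_sat_density_sd") %in% names(df)))
})
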