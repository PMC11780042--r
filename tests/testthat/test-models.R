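# The built-in CNN engine and the two architectures.

test_that("network gradients agree with finite differences", {
  ns <- asNamespace("bodycomp")
  set.seed(5)
  g <- ns$graph_new(2L)
  dc <- function(g, x, f) ns$g_relu(g, ns$g_conv(g, x, 3, f))
  x1 <- dc(g, 1L, 3)
  sk <- ns$res_path(g, x1, 3, 2)          # exercises conv1 + add
  xp <- ns$g_maxpool(g, x1)
  xb <- ns$mres_block(g, xp, 4)           # exercises concat + shortcut
  xu <- ns$g_relu(g, ns$g_conv(g, ns$g_upsample(g, xb), 3, 3))
  xc <- ns$g_concat(g, xu, sk)
  logits <- ns$g_conv(g, xc, 1, 3)
  w <- ns$init_weights(g$wspec)
  nodes <- ns$engine_nodes(g)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))

  for (loss in c("mse", "ce_dice")) {
    if (loss == "mse") {
      t <- array(runif(16 * 16 * 3), c(16, 16, 3))
    } else {
      lab <- matrix(sample(0:2, 256, TRUE), 16, 16)
      t <- array(0, c(16, 16, 3))
      for (c in 1:3) t[, , c] <- lab == (c - 1)
    }
    gr <- ns$cnn_grad_cpp(nodes, w, x, t, loss, 1)
    eps <- 1e-6
    for (chk in 1:25) {
      wi <- sample(length(w), 1)
      ei <- sample(length(w[[wi]]$W), 1)
      wp <- w; wp[[wi]]$W[ei] <- wp[[wi]]$W[ei] + eps
      wm <- w; wm[[wi]]$W[ei] <- wm[[wi]]$W[ei] - eps
      num <- (ns$cnn_loss_cpp(nodes, wp, list(x), list(t), loss, 1) -
                ns$cnn_loss_cpp(nodes, wm, list(x), list(t), loss, 1)) / (2 * eps)
      ana <- gr$gW[[wi]][ei]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-3)
    }
  }
})

test_that("multiresunet maps 3-channel input to a [0,1] heatmap", {
  m <- build_multiresunet(c(32, 64, 3), base = 2, seed = 9)
  out <- predict(m, array(0, c(32, 64, 3)))
  expect_equal(dim(out), c(32L, 64L))
  expect_true(all(is.finite(out)) && all(out >= 0) && all(out <= 1))
  expect_error(build_multiresunet(c(30, 64, 3), base = 2), "divisible")
})

test_that("unet produces per-pixel probabilities summing to one", {
  m <- build_unet(c(32, 32, 2), n_classes = 4, base = 2, level = "L3",
                  classes = level_classes("L3"), seed = 9)
  set.seed(1)
  out <- predict(m, array(rnorm(32 * 32 * 2), c(32, 32, 2)))
  expect_equal(dim(out), c(32L, 32L, 4L))
  expect_lt(max(abs(apply(out, c(1, 2), sum) - 1)), 1e-5)
  expect_error(build_unet(c(33, 32, 2), 4), "divisible")
})

test_that("a tiny model overfits two samples (training loss collapses)", {
  set.seed(4)
  # two fixed localization-style samples: input channels correlated with the
  # target blob positions
  mk <- function(v0) {
    x <- array(0, c(32, 64, 3))
    u <- matrix(0:31, 32, 64); v <- matrix(0:63, 32, 64, byrow = TRUE)
    x[, , 1] <- exp(-((u - 16)^2 + (v - v0)^2) / 18)
    x[, , 2] <- 0.3
    y <- exp(-((u - 16)^2 + (v - v0)^2) / (2 * 16))
    dim(y) <- c(32, 64, 1)
    list(x = x, y = y / max(y))
  }
  d <- list(mk(18), mk(45))
  m <- build_multiresunet(c(32, 64, 3), base = 2, seed = 11)
  m <- cnn_fit(m, lapply(d, `[[`, "x"), lapply(d, `[[`, "y"),
               epochs = 100, batch = 2, lr = 1e-3, validation_frac = 0, seed = 12)
  expect_lt(tail(m$history, 1), 0.1 * m$history[1])
})

test_that("training is deterministic under a fixed seed", {
  set.seed(8)
  xs <- lapply(1:4, function(i) array(runif(32 * 32 * 1), c(32, 32, 1)))
  ys <- lapply(1:4, function(i) {
    lab <- matrix(as.integer(xs[[i]][, , 1] > 0.5), 32, 32)
    y <- array(0, c(32, 32, 2)); y[, , 1] <- lab == 0; y[, , 2] <- lab == 1
    y
  })
  fit_once <- function() {
    m <- build_unet(c(32, 32, 1), 2, base = 2, level = "L1",
                    classes = c("background", "trabecular"), seed = 5)
    cnn_fit(m, xs, ys, epochs = 3, batch = 2, lr = 1e-3,
            validation_frac = 0, seed = 6)
  }
  m1 <- fit_once(); m2 <- fit_once()
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
})

test_that("predict_mask breaks probability ties toward the lower class", {
  # which.max returns the first maximum, i.e. the lower class index
  m <- build_unet(c(32, 32, 1), 3, base = 2, level = "L1",
                  classes = level_classes("L1"), seed = 2)
  p <- array(1 / 3, c(4, 4, 3))   # exact three-way tie
  lab <- apply(p, c(1, 2), which.max) - 1L
  expect_true(all(lab == 0L))
  # a uniform probability-1 class gives a uniform mask through the model API
  img <- array(0, c(32, 32, 1))
  mask <- predict_mask(m, img)
  expect_true(all(mask$labels %in% 0:2))
  expect_identical(mask$classes, level_classes("L1"))
})

test_that("model save/load round-trips weights and manifest", {
  m <- build_multiresunet(c(32, 64, 3), base = 2, seed = 3)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$weights, m$weights)
  expect_identical(m2$manifest, m$manifest)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_model(bad), "not a bodycomp model")
})
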