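# Network architectures: a MultiResUNet for heatmap-based vertebra
# localization and a plain U-Net for axial-slice segmentation.  Both are
# 4-level encoder-decoder graphs; spatial dims must be divisible by 2^4.

# MultiRes block: three chained 3x3 convolutions (factorizing the 5x5 and 7x7
# receptive fields), their concatenation, and a 1x1 residual shortcut.
# Filter split follows the usual alpha scaling: W = alpha * U with branches
# ~ W/6, W/3, W/2.
mres_block <- function(g, x, U, alpha = 1.67) {
  W <- alpha * U
  f <- pmax(1L, as.integer(round(c(W / 6, W / 3, W / 2))))
  a <- g_relu(g, g_conv(g, x, 3, f[1]))
  b <- g_relu(g, g_conv(g, a, 3, f[2]))
  cc <- g_relu(g, g_conv(g, b, 3, f[3]))
  cat1 <- g_concat(g, a, b)
  cat2 <- g_concat(g, cat1, cc)
  sh <- g_conv(g, x, 1, sum(f))
  g_relu(g, g_add(g, cat2, sh))
}

# Res Path: the skip connection is refined by n residual conv blocks
# (3x3 conv + 1x1 shortcut), n = 4,3,2,1 at successive depths.
res_path <- function(g, x, f, n) {
  for (i in seq_len(n)) {
    x <- g_relu(g, g_add(g, g_conv(g, x, 3, f), g_conv(g, x, 1, f)))
  }
  x
}

check_grid <- function(shape) {
  if (any(shape[1:2] %% 16L != 0L))
    stop("input shape ", paste(shape[1:2], collapse = "x"),
         " must be divisible by 2^4")
}

#' Build the MultiResUNet heatmap model
#'
#' Encoder-decoder with 4 MultiRes blocks per side connected by Res Paths
#' (4, 3, 2, 1 residual blocks at successive depths), a MultiRes bottleneck,
#' nearest-neighbour upsampling followed by convolution in the decoder, and a
#' final 1x1 convolution with sigmoid activation producing a single
#' non-negative heatmap channel. Trained with pixelwise mean squared error.
#'
#' @param input_shape c(H, W, channels); H and W must be divisible by 16.
#' @param base base filter count of the first MultiRes block (doubled at each
#'   depth); small values (4-8) train in minutes on one CPU.
#' @param seed integer seed for weight initialization.
#' @param heatmap_prior expected mean activation of the target heatmap; the
#'   output bias is initialized to its logit so that early training starts
#'   from the low-occupancy prior instead of collapsing the sparse heatmap
#'   toward its mean (which silences ReLUs and stalls optimization).
#' @return an untrained `bodycomp_cnn` model.
#' @export
build_multiresunet <- function(input_shape = c(128, 256, 3), base = 6, seed = 1,
                               heatmap_prior = 0.05) {
  check_grid(input_shape)
  g <- graph_new(input_shape[3])
  x <- 1L
  skips <- integer(0)
  for (d in 1:4) {
    m <- mres_block(g, x, base * 2^(d - 1))
    skips[d] <- res_path(g, m, g$ch[m], 5L - d)
    x <- g_maxpool(g, m)
  }
  x <- mres_block(g, x, base * 16)
  for (d in 4:1) {
    up <- g_relu(g, g_conv(g, g_upsample(g, x), 3, g$ch[skips[d]]))
    x <- mres_block(g, g_concat(g, up, skips[d]), base * 2^(d - 1))
  }
  logits <- g_conv(g, x, 1, 1)
  weights <- with_seed(seed, init_weights(g$wspec))
  weights[[length(weights)]]$b[] <- log(heatmap_prior / (1 - heatmap_prior))
  new_cnn_model(g, weights, activation = "sigmoid", loss = "mse",
                input_shape = as.integer(input_shape),
                manifest = list(architecture = "multiresunet", base = base,
                                grid = as.integer(input_shape[1:2]),
                                task = "heatmap"))
}

#' Build a U-Net segmentation model
#'
#' Plain encoder-decoder with 4 double-convolution blocks per side, a middle
#' block, nearest-neighbour upsampling in the decoder, direct skip
#' concatenation, and a final 1x1 convolution with per-pixel softmax over
#' `n_classes` mutually exclusive classes. Trained with cross-entropy plus
#' soft-Dice loss.
#'
#' @param input_shape c(H, W, channels); H and W must be divisible by 16.
#' @param n_classes number of output classes (includes background).
#' @param base filter count of the first block (doubled at each depth).
#' @param level anatomical level tag carried in the manifest ("L1" or "L3").
#' @param classes class vocabulary carried in the manifest.
#' @param seed integer seed for weight initialization.
#' @param class_priors optional vector of expected class frequencies; the
#'   output biases are initialized to their logs so that training starts from
#'   the marginal class distribution. Without this, the large background
#'   class drives early updates that collapse the network onto
#'   all-background, from which gradient descent does not recover.
#' @return an untrained `bodycomp_cnn` model.
#' @export
build_unet <- function(input_shape, n_classes, base = 8,
                       level = NULL, classes = NULL, seed = 1,
                       class_priors = NULL) {
  check_grid(input_shape)
  stopifnot(n_classes >= 2)
  double_conv <- function(g, x, f) {
    g_relu(g, g_conv(g, g_relu(g, g_conv(g, x, 3, f)), 3, f))
  }
  g <- graph_new(input_shape[3])
  x <- 1L
  skips <- integer(0)
  for (d in 1:4) {
    m <- double_conv(g, x, base * 2^(d - 1))
    skips[d] <- m
    x <- g_maxpool(g, m)
  }
  x <- double_conv(g, x, base * 16)
  for (d in 4:1) {
    up <- g_relu(g, g_conv(g, g_upsample(g, x), 3, g$ch[skips[d]]))
    x <- double_conv(g, g_concat(g, up, skips[d]), base * 2^(d - 1))
  }
  logits <- g_conv(g, x, 1, n_classes)
  weights <- with_seed(seed, init_weights(g$wspec))
  if (!is.null(class_priors)) {
    stopifnot(length(class_priors) == n_classes, all(class_priors > 0))
    weights[[length(weights)]]$b <- log(as.numeric(class_priors))
  }
  new_cnn_model(g, weights, activation = "softmax", loss = "ce_dice",
                input_shape = as.integer(input_shape),
                manifest = list(architecture = "unet", base = base,
                                grid = as.integer(input_shape[1:2]),
                                n_classes = as.integer(n_classes),
                                level = level, classes = classes,
                                task = "segmentation"))
}
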