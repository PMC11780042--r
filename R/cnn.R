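# Graph builder and fitting interface for the built-in CNN engine (src/cnn.cpp).
# A network is a flat, topologically ordered list of primitive-op nodes plus a
# parallel list of convolution weights; forward/backward and Adam live in C++.

graph_new <- function(in_channels) {
  g <- new.env(parent = emptyenv())
  g$nodes <- list(list(op = "input", in_ = integer(0), w = 0L, k = 0L))
  g$ch <- in_channels
  g$wspec <- list()
  g
}

g_node <- function(g, op, inputs, w = 0L, k = 0L, ch) {
  g$nodes[[length(g$nodes) + 1L]] <- list(op = op, in_ = as.integer(inputs),
                                          w = as.integer(w), k = as.integer(k))
  g$ch <- c(g$ch, ch)
  length(g$nodes)
}

# Node-id arguments are forced before g$ch is read: they may be nested
# builder calls that mutate the graph.
g_conv <- function(g, x, k, cout) {
  force(x)
  cin <- g$ch[x]
  g$wspec[[length(g$wspec) + 1L]] <- list(k = k, cin = cin, cout = cout)
  g_node(g, "conv", x, w = length(g$wspec), k = k, ch = cout)
}

g_relu <- function(g, x) { force(x); g_node(g, "relu", x, ch = g$ch[x]) }
g_maxpool <- function(g, x) { force(x); g_node(g, "maxpool", x, ch = g$ch[x]) }
g_upsample <- function(g, x) { force(x); g_node(g, "upsample", x, ch = g$ch[x]) }
g_concat <- function(g, a, b) {
  force(a); force(b)
  g_node(g, "concat", c(a, b), ch = g$ch[a] + g$ch[b])
}
g_add <- function(g, a, b) {
  force(a); force(b)
  stopifnot(g$ch[a] == g$ch[b])
  g_node(g, "add", c(a, b), ch = g$ch[a])
}

# He-style initialization under the caller's RNG stream.
init_weights <- function(wspec) {
  lapply(wspec, function(s) {
    fan_in <- s$k * s$k * s$cin
    list(W = matrix(rnorm(s$cout * fan_in, sd = sqrt(2 / fan_in)),
                    nrow = s$cout, ncol = fan_in),
         b = numeric(s$cout))
  })
}

# Engine expects nodes with fields op/in/w/k.
engine_nodes <- function(g) {
  lapply(g$nodes, function(n) list(op = n$op, `in` = n$in_, w = n$w, k = n$k))
}

new_cnn_model <- function(graph, weights, activation, loss, input_shape, manifest) {
  structure(list(nodes = engine_nodes(graph), weights = weights,
                 activation = activation, loss = loss,
                 input_shape = input_shape,
                 manifest = manifest, history = numeric(0)),
            class = "bodycomp_cnn")
}

#' @export
print.bodycomp_cnn <- function(x, ...) {
  cat(sprintf("<bodycomp_cnn> %s: input %s, %d conv layers, %d parameters\n",
              x$manifest$architecture,
              paste(x$input_shape, collapse = "x"),
              length(x$weights),
              sum(vapply(x$weights, function(w) length(w$W) + length(w$b), 0))))
  invisible(x)
}

as_input_array <- function(x, shape) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (!identical(dim(x)[1:2], as.integer(shape[1:2])) ||
      dim(x)[3] != shape[3])
    stop("input shape ", paste(dim(x), collapse = "x"),
         " does not match model input ", paste(shape, collapse = "x"))
  x
}

#' Forward pass of a built-in CNN model
#'
#' @param object a `bodycomp_cnn` model.
#' @param x input array (H x W x C, or H x W for single-channel models).
#' @param ... unused.
#' @return array of model outputs (sigmoid or per-class softmax activations).
#' @export
predict.bodycomp_cnn <- function(object, x, ...) {
  x <- as_input_array(x, object$input_shape)
  out <- cnn_forward_cpp(object$nodes, object$weights, x, object$activation)
  if (dim(out)[3] == 1L) dim(out) <- dim(out)[1:2]
  out
}

#' Train a built-in CNN model
#'
#' Mini-batch Adam with optional early stopping on a held-out validation
#' subset. All shuffling and the validation split are driven by `seed`, so a
#' fit is fully reproducible.
#'
#' @param model a `bodycomp_cnn` model (weights are the starting point).
#' @param x,y lists of input / target arrays of equal length.
#' @param epochs maximum number of epochs.
#' @param batch mini-batch size.
#' @param lr Adam learning rate.
#' @param dice_weight weight of the soft-Dice term (segmentation loss only).
#' @param validation_frac fraction of samples held out for early stopping
#'   (0 disables early stopping).
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed for shuffling and the validation split.
#' @param verbose print per-epoch losses.
#' @return the fitted model, with `$history` holding per-epoch training loss.
#' @export
cnn_fit <- function(model, x, y, epochs = 30, batch = 8, lr = 1e-3,
                    dice_weight = if (model$loss == "ce_dice") 1 else 0,
                    validation_frac = 0.1, patience = 8, seed = 1,
                    verbose = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  x <- lapply(x, as_input_array, shape = model$input_shape)
  loss <- model$loss
  n <- length(x)

  with_seed(seed, {
    n_val <- if (validation_frac > 0 && n >= 5) max(1L, floor(validation_frac * n)) else 0L
    idx <- sample.int(n)
    val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(idx, val_idx)
    ntr <- length(tr_idx)
    orders <- t(vapply(seq_len(epochs), function(e) sample(tr_idx),
                       integer(ntr)))  # epochs x ntr, values index x/y

    # remap to 1..ntr over the training subset
    xtr <- x[tr_idx]; ytr <- y[tr_idx]
    remap <- match(as.vector(orders), tr_idx)
    orders <- matrix(remap, nrow = epochs)

    weights <- model$weights
    adam <- NULL
    best <- list(loss = Inf, weights = weights)
    wait <- 0L
    hist <- numeric(0)
    for (e in seq_len(epochs)) {
      fit <- cnn_train_cpp(model$nodes, weights, xtr, ytr, loss, dice_weight,
                           as.integer(batch), lr, orders[e, , drop = FALSE], adam)
      weights <- fit$weights
      adam <- fit$adam
      hist <- c(hist, fit$loss)
      if (n_val > 0) {
        vl <- cnn_loss_cpp(model$nodes, weights, x[val_idx], y[val_idx],
                           loss, dice_weight)
        if (verbose)
          message(sprintf("epoch %d: train %.5g  val %.5g", e, fit$loss, vl))
        if (vl < best$loss - 1e-9) {
          best <- list(loss = vl, weights = weights)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      } else if (verbose) {
        message(sprintf("epoch %d: train %.5g", e, fit$loss))
      }
    }
    model$weights <- if (n_val > 0) best$weights else weights
    model$history <- hist
    model
  })
}

#' Save / load a trained model
#'
#' Models are stored with a manifest (architecture, input grid, class
#' vocabulary, anatomical level) that is checked on load and again before
#' inference, so that e.g. an L1 model cannot silently be applied to L3
#' inputs.
#'
#' @param model a `bodycomp_cnn` model.
#' @param path file path.
#' @return `load_model` returns the model; `save_model` returns `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "bodycomp_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "bodycomp_cnn") || is.null(model$manifest))
    stop("not a bodycomp model file: ", path)
  model
}
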