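#' Initialize a feed-forward softmax network
#'
#' Builds a fully connected network mapping the 12 feature-scaled
#' concentrations to 3 class probabilities.  Each node computes
#' \eqn{y = f(b + \sum_n x_n w_n)} with a rectifier (ReLU) on the hidden
#' layers and a softmax on the output layer.  Weights are drawn from a
#' fan-in-scaled uniform distribution,
#' \eqn{U(-\sqrt{6 / n_{in}}, \sqrt{6 / n_{in}})}, biases start at zero;
#' the draw is reproducible from `seed`.
#'
#' @param layer_sizes Integer vector of layer widths from input to output;
#'   default `c(12, 64, 64, 64, 3)` (three hidden layers — deeper
#'   networks showed no accuracy or loss improvement on this problem).
#' @param seed Seed for the weight draw.
#' @return An object of class `mlp` with per-layer weight matrices `w`
#'   and bias vectors `b`.
#' @examples
#' net <- init_network(c(12, 8, 3), seed = 1)
#' sapply(net$w, dim)
#' @export
init_network <- function(layer_sizes = c(12L, 64L, 64L, 64L, 3L),
                         seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2 || anyNA(layer_sizes) || any(layer_sizes < 1)) {
    stop("layer_sizes must be >= 2 positive integers")
  }
  set.seed(spawn_seeds(seed, 1L))
  nl <- length(layer_sizes) - 1L
  w <- vector("list", nl)
  b <- vector("list", nl)
  for (l in seq_len(nl)) {
    fan_in <- layer_sizes[l]
    lim <- sqrt(6 / fan_in)
    w[[l]] <- matrix(stats::runif(fan_in * layer_sizes[l + 1], -lim, lim),
                     nrow = fan_in)
    b[[l]] <- numeric(layer_sizes[l + 1])
  }
  structure(list(layer_sizes = layer_sizes, w = w, b = b,
                 hidden_activation = "relu",
                 output_activation = "softmax"),
            class = "mlp")
}

# row-wise softmax with max subtraction for numerical stability
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass through the network
#'
#' Propagates a batch of feature vectors layer by layer: each layer
#' computes the affine map `x %*% w + b` followed by the rectifier on
#' hidden layers and a row-wise softmax on the output, yielding the
#' probability that each profile arose from each of the three absorption
#' shapes.
#'
#' @param net An `mlp` from [init_network()].
#' @param x Numeric matrix (profiles x features) or a single feature
#'   vector.
#' @param keep_hidden Return intermediate activations (used by the
#'   training backward pass).
#' @return Matrix of class probabilities (rows sum to 1), columns in the
#'   canonical label order; with `keep_hidden = TRUE`, a list with
#'   `probs`, `z` (pre-activations) and `a` (activations).
#' @export
forward <- function(net, x, keep_hidden = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != net$layer_sizes[1]) {
    stop(sprintf("feature length %d does not match network input size %d",
                 ncol(x), net$layer_sizes[1]))
  }
  nl <- length(net$w)
  a <- vector("list", nl + 1)
  z <- vector("list", nl)
  a[[1]] <- x
  for (l in seq_len(nl)) {
    z[[l]] <- sweep(a[[l]] %*% net$w[[l]], 2, net$b[[l]], "+")
    a[[l + 1]] <- if (l < nl) pmax(z[[l]], 0) else softmax_rows(z[[l]])
  }
  probs <- a[[nl + 1]]
  colnames(probs) <- shape_levels()
  if (keep_hidden) list(probs = probs, z = z, a = a) else probs
}

#' Mean categorical cross-entropy
#'
#' Mean over the batch of the negative natural log of the probability
#' assigned to the true class.  Probabilities are clamped below at 1e-12
#' before the log.
#'
#' @param probs Matrix of class probabilities (rows = profiles).
#' @param y One-hot label matrix of the same dimensions.
#' @return Scalar loss value.
#' @examples
#' cross_entropy(matrix(1/3, 2, 3), rbind(c(1,0,0), c(0,1,0)))  # log(3)
#' @export
cross_entropy <- function(probs, y) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (!all(dim(probs) == dim(y))) stop("probs and y dimensions differ")
  p_true <- rowSums(probs * y)
  mean(-log(pmax(p_true, 1e-12)))
}

# classification accuracy of a probability matrix against one-hot labels
accuracy_probs <- function(probs, y) {
  mean(max.col(probs, ties.method = "first") ==
         max.col(y, ties.method = "first"))
}

#' Training configuration
#'
#' @param batch_size Mini-batch size (default 32).
#' @param epochs Training epochs (default 100).
#' @param learning_rate Step size of the adaptive moment-estimation
#'   (Adam) optimizer (default 0.001).
#' @param beta1,beta2,adam_eps Adam moment-decay and stabilization
#'   constants (conventional defaults).
#' @param seed Seed controlling weight initialization and the per-epoch
#'   shuffling stream.
#' @return A list of class `training_config`.
#' @export
training_config <- function(batch_size = 32L, epochs = 100L,
                            learning_rate = 1e-3, beta1 = 0.9,
                            beta2 = 0.999, adam_eps = 1e-8, seed = 1L) {
  if (batch_size < 1 || epochs < 1) stop("batch_size and epochs must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, adam_eps = adam_eps,
                 seed = as.integer(seed)),
            class = "training_config")
}

# gradients of the mean cross-entropy wrt all weights and biases,
# computed by backpropagation from a forward pass that kept activations
mlp_gradients <- function(net, x, y) {
  fw <- forward(net, x, keep_hidden = TRUE)
  nl <- length(net$w)
  n <- nrow(x)
  gw <- vector("list", nl)
  gb <- vector("list", nl)
  delta <- (fw$probs - y) / n          # softmax + cross-entropy jacobian
  for (l in rev(seq_len(nl))) {
    gw[[l]] <- crossprod(fw$a[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$w[[l]])) * (fw$z[[l - 1]] > 0)
    }
  }
  list(w = gw, b = gb, loss = cross_entropy(fw$probs, y))
}

#' Train the network by mini-batch gradient descent
#'
#' Minimizes the categorical cross-entropy with the Adam optimizer,
#' shuffling the training order each epoch from a seeded stream.  The
#' whole run is deterministic given the configuration seed and
#' single-threaded linear algebra.
#'
#' @param net An `mlp` from [init_network()].
#' @param x,y Training feature matrix (values in \[0, 1\]) and one-hot
#'   labels.
#' @param x_val,y_val Optional validation split, monitored per epoch.
#' @param cfg A [training_config()].
#' @param verbose Print a progress line every 10 epochs.
#' @return List with the trained `net` and a `history` data frame
#'   (epoch, train loss/accuracy, validation loss/accuracy).
#' @export
train_network <- function(net, x, y, x_val = NULL, y_val = NULL,
                          cfg = training_config(), verbose = FALSE) {
  nl <- length(net$w)
  mw <- lapply(net$w, function(w) w * 0); vw <- mw
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  n <- nrow(x)
  history <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                        train_acc = NA_real_, val_loss = NA_real_,
                        val_acc = NA_real_)
  set.seed(spawn_seeds(cfg$seed, 1L))
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      g <- mlp_gradients(net, x[idx, , drop = FALSE], y[idx, , drop = FALSE])
      if (!is.finite(g$loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      }
      step <- step + 1L
      c1 <- 1 - cfg$beta1^step
      c2 <- 1 - cfg$beta2^step
      for (l in seq_len(nl)) {
        mw[[l]] <- cfg$beta1 * mw[[l]] + (1 - cfg$beta1) * g$w[[l]]
        vw[[l]] <- cfg$beta2 * vw[[l]] + (1 - cfg$beta2) * g$w[[l]]^2
        net$w[[l]] <- net$w[[l]] - cfg$learning_rate * (mw[[l]] / c1) /
          (sqrt(vw[[l]] / c2) + cfg$adam_eps)
        mb[[l]] <- cfg$beta1 * mb[[l]] + (1 - cfg$beta1) * g$b[[l]]
        vb[[l]] <- cfg$beta2 * vb[[l]] + (1 - cfg$beta2) * g$b[[l]]^2
        net$b[[l]] <- net$b[[l]] - cfg$learning_rate * (mb[[l]] / c1) /
          (sqrt(vb[[l]] / c2) + cfg$adam_eps)
      }
    }
    p_tr <- forward(net, x)
    history$train_loss[epoch] <- cross_entropy(p_tr, y)
    history$train_acc[epoch] <- accuracy_probs(p_tr, y)
    if (!is.null(x_val)) {
      p_va <- forward(net, x_val)
      history$val_loss[epoch] <- cross_entropy(p_va, y_val)
      history$val_acc[epoch] <- accuracy_probs(p_va, y_val)
    }
    if (verbose && epoch %% 10 == 0) {
      message(sprintf(
        "epoch %3d  train loss %.4f acc %.4f  val loss %.4f acc %.4f",
        epoch, history$train_loss[epoch], history$train_acc[epoch],
        history$val_loss[epoch], history$val_acc[epoch]))
    }
  }
  list(net = net, history = history)
}

#' Classify profiles with a trained network
#'
#' Runs the forward pass and assigns each profile to the class with the
#' highest probability.  Exact ties are broken toward the first class in
#' the canonical order (first_order, erlang, split_peak) and flagged.
#'
#' @param net A trained `mlp`.
#' @param x Feature matrix or single feature vector.
#' @return data.frame with the three class probabilities, the
#'   `assigned` label and a logical `tie` flag.
#' @examples
#' net <- init_network(c(12, 3), seed = 1)
#' classify(net, matrix(runif(24), 2))
#' @export
classify <- function(net, x) {
  probs <- forward(net, x)
  idx <- max.col(probs, ties.method = "first")
  mx <- probs[cbind(seq_len(nrow(probs)), idx)]
  tie <- rowSums(abs(probs - mx) < 1e-12) > 1
  out <- as.data.frame(probs)
  names(out) <- paste0("p_", shape_levels())
  out$assigned <- factor(shape_levels()[idx], levels = shape_levels())
  out$tie <- tie
  out
}

#' Save and load a network artifact
#'
#' The artifact is self-describing JSON carrying a format version, the
#' layer sizes, activation names and all weights; numbers are serialized
#' with 17 significant digits so that save -> load -> forward reproduces
#' the original forward pass bit-exactly.
#'
#' @param net An `mlp`.
#' @param path Output file path.
#' @return `path` (save) or the restored `mlp` (load).
#' @export
save_model <- function(net, path) {
  art <- list(
    format = "pkprescreen-mlp",
    version = 1L,
    layer_sizes = net$layer_sizes,
    hidden_activation = net$hidden_activation,
    output_activation = net$output_activation,
    w = lapply(net$w, function(m) {
      list(dim = dim(m), data = sprintf("%.17g", as.vector(m)))
    }),
    b = lapply(net$b, function(v) sprintf("%.17g", v)))
  jsonlite::write_json(art, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  art <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  for (f in c("format", "version", "layer_sizes", "w", "b")) {
    if (is.null(art[[f]])) stop(sprintf("model artifact lacks field '%s'", f))
  }
  if (!identical(art$format, "pkprescreen-mlp")) {
    stop(sprintf("unrecognized model artifact format '%s'", art$format))
  }
  if (art$version != 1L) {
    stop(sprintf("unsupported model artifact version %s", art$version))
  }
  sizes <- as.integer(art$layer_sizes)
  w <- vector("list", length(art$w))
  b <- vector("list", length(art$b))
  for (l in seq_along(art$w)) {
    d <- as.integer(art$w[[l]]$dim)
    vals <- as.numeric(art$w[[l]]$data)
    if (length(vals) != prod(d) || d[1] != sizes[l] || d[2] != sizes[l + 1]) {
      stop(sprintf("layer %d weights: declared dim %s inconsistent with data",
                   l, paste(d, collapse = "x")))
    }
    w[[l]] <- matrix(vals, nrow = d[1], ncol = d[2])
    b[[l]] <- as.numeric(art$b[[l]])
    if (length(b[[l]]) != sizes[l + 1]) {
      stop(sprintf("layer %d biases: length %d, expected %d",
                   l, length(b[[l]]), sizes[l + 1]))
    }
  }
  structure(list(layer_sizes = sizes, w = w, b = b,
                 hidden_activation = art$hidden_activation,
                 output_activation = art$output_activation),
            class = "mlp")
}
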