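#' Classifier architecture configuration
#'
#' Two backbones are available. `small_cnn` (the default) is a compact
#' three-block network — 3x3 convolution + ReLU + 2x2 max pooling with 16,
#' 32 and 64 filters — that trains from scratch in minutes on a CPU.
#' `vgg16` instantiates the classical 13-convolution VGG16 stack (randomly
#' initialised; `backbone_frozen` keeps its convolution weights fixed
#' during training). Either backbone feeds global average pooling, one
#' ReLU-activated dense hidden layer, and a softmax output over the
#' species.
#'
#' @param n_classes number of species (output dimension).
#' @param backbone `"small_cnn"` or `"vgg16"`.
#' @param input_size `(h, w)` fed to the network; default 64x64 for
#'   `small_cnn`, 224x224 for `vgg16`; at least 32x32 and divisible by the
#'   backbone's total pooling factor.
#' @param hidden_units width of the dense hidden layer (default 64 for
#'   `small_cnn`, 256 for `vgg16`).
#' @param backbone_frozen freeze convolution weights (`vgg16` only).
#' @return a `model_config` list.
#' @export
model_config <- function(n_classes, backbone = c("small_cnn", "vgg16"),
                         input_size = NULL, hidden_units = NULL,
                         backbone_frozen = TRUE) {
  if (is.character(backbone) && length(backbone) == 1 &&
      !backbone %in% c("small_cnn", "vgg16"))
    stop("unknown backbone: ", backbone)
  backbone <- match.arg(backbone)
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (is.null(input_size))
    input_size <- if (backbone == "vgg16") c(224L, 224L) else c(64L, 64L)
  if (any(input_size < 32)) stop("input_size must be at least 32x32")
  if (is.null(hidden_units))
    hidden_units <- if (backbone == "vgg16") 256L else 64L
  blocks <- if (backbone == "vgg16") {
    list(c(64, 64), c(128, 128), c(256, 256, 256),
         c(512, 512, 512), c(512, 512, 512))
  } else {
    list(16, 32, 64)
  }
  pf <- 2^length(blocks)
  if (any(input_size %% pf != 0))
    stop("input_size must be divisible by ", pf, " for this backbone")
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 hidden_units = as.integer(hidden_units),
                 backbone_frozen = isTRUE(backbone_frozen) &&
                   backbone == "vgg16",
                 blocks = blocks),
            class = "model_config")
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

#' Build an untrained colony classifier
#'
#' Weights use He-normal initialisation driven entirely by `seed`, so two
#' builds with the same configuration and seed are identical.
#'
#' @param config a [model_config()].
#' @param seed integer RNG seed for weight initialisation.
#' @return a `colony_cnn` model object.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  run_with_seed(seed, {
    k <- 3L
    conv <- list()
    cin <- 3L
    for (b in config$blocks) for (f in b) {
      fan_in <- k * k * cin
      conv[[length(conv) + 1L]] <-
        list(W = he_init(fan_in, f, fan_in), b = numeric(f))
      cin <- as.integer(f)
    }
    g <- cin  # channels entering global average pooling
    dense <- list(W1 = he_init(g, config$hidden_units, g),
                  b1 = numeric(config$hidden_units),
                  W2 = he_init(config$hidden_units, config$n_classes,
                               config$hidden_units),
                  b2 = numeric(config$n_classes))
    structure(list(config = config, labels = NULL, conv = conv,
                   dense = dense),
              class = "colony_cnn")
  })
}

#' @export
print.colony_cnn <- function(x, ...) {
  cat("colony classifier:", x$config$backbone, "backbone,",
      paste(x$config$input_size, collapse = "x"), "input,",
      x$config$n_classes, "classes\n")
  if (!is.null(x$labels)) cat("labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

softmax_rows <- function(s) {
  s <- s - apply(s, 1, max)
  e <- exp(s)
  e / rowSums(e)
}

# Forward pass over a (h, w, 3, N) batch in [0, 1].
# Returns probs (N x K) and, when keep_cache, everything backward needs.
forward_cnn <- function(model, x, keep_cache = FALSE) {
  a <- x
  cache <- if (keep_cache) list() else NULL
  li <- 0L
  for (b in model$config$blocks) {
    for (f in b) {
      li <- li + 1L
      p <- model$conv[[li]]
      z <- cpp_conv_fw(a, p$W, p$b)
      mask <- z > 0
      if (keep_cache) cache[[length(cache) + 1L]] <-
        list(type = "conv", i = li, input = a, mask = mask)
      a <- z * mask
    }
    pl <- cpp_maxpool_fw(a)
    if (keep_cache) cache[[length(cache) + 1L]] <-
      list(type = "pool", idx = pl$idx, h = dim(a)[1], w = dim(a)[2])
    a <- pl$y
  }
  d <- dim(a)                              # (h, w, C, N)
  hw <- d[1] * d[2]
  flat <- a; dim(flat) <- c(hw, d[3] * d[4])
  g <- matrix(colMeans(flat), d[3], d[4])  # C x N
  g <- t(g)                                # N x C (global average pooling)
  z1 <- sweep(g %*% model$dense$W1, 2, model$dense$b1, "+")
  m1 <- z1 > 0
  h1 <- z1 * m1
  s <- sweep(h1 %*% model$dense$W2, 2, model$dense$b2, "+")
  probs <- softmax_rows(s)
  if (keep_cache)
    list(probs = probs, cache = cache, g = g, m1 = m1, h1 = h1,
         feat_dim = d)
  else list(probs = probs)
}

# Backward pass for mean cross-entropy; y is an N x K one-hot matrix.
# Returns gradients in the same shape as get_params(model).
backward_cnn <- function(model, fw, y) {
  n <- nrow(y)
  ds <- (fw$probs - y) / n
  gr <- list(dense = list(
    W2 = t(fw$h1) %*% ds, b2 = colSums(ds),
    W1 = NULL, b1 = NULL), conv = vector("list", length(model$conv)))
  dh1 <- ds %*% t(model$dense$W2)
  dz1 <- dh1 * fw$m1
  gr$dense$W1 <- t(fw$g) %*% dz1
  gr$dense$b1 <- colSums(dz1)
  dg <- dz1 %*% t(model$dense$W1)          # N x C
  d <- fw$feat_dim
  hw <- d[1] * d[2]
  da <- array(rep(as.vector(t(dg)) / hw, each = hw), d)
  frozen <- model$config$backbone_frozen
  for (entry in rev(fw$cache)) {
    if (entry$type == "pool") {
      da <- cpp_maxpool_bw(entry$idx, da, entry$h, entry$w)
    } else {
      dz <- da * entry$mask
      if (frozen) {
        # still need dx to keep propagating, but skip weight grads
        bw <- cpp_conv_bw(entry$input, model$conv[[entry$i]]$W, dz)
        gr$conv[[entry$i]] <- list(W = bw$dw * 0, b = bw$db * 0)
        da <- bw$dx
      } else {
        bw <- cpp_conv_bw(entry$input, model$conv[[entry$i]]$W, dz)
        gr$conv[[entry$i]] <- list(W = bw$dw, b = bw$db)
        da <- bw$dx
      }
    }
  }
  gr
}

cross_entropy <- function(probs, y_idx) {
  p <- pmax(probs[cbind(seq_along(y_idx), y_idx)], 1e-12)
  -mean(log(p))
}

#' Classify one plate image
#'
#' Resizes the image to the model's input size and runs a forward pass.
#' The predicted label is the argmax of the softmax output; ties resolve
#' to the earlier label in sorted label order.
#'
#' @param object a trained `colony_cnn`.
#' @param image an `rgb_image` (any size) or `(h, w, 3)` array in
#'   `[0, 255]`.
#' @param ... unused.
#' @return named probability vector (sums to 1) with attributes
#'   `predicted` (label) and `index`.
#' @export
predict.colony_cnn <- function(object, image, ...) {
  if (!is_rgb_image(image)) stop("predict needs an (H, W, 3) RGB image")
  sz <- object$config$input_size
  img <- resize_rgb(as_rgb_image(unclass(image)), sz[1], sz[2])
  x <- array(unclass(img) / 255, c(sz[1], sz[2], 3, 1))
  p <- forward_cnn(object, x)$probs[1, ]
  labels <- object$labels
  if (is.null(labels)) labels <- paste0("class_", seq_along(p))
  names(p) <- labels
  idx <- which.max(p)
  structure(p, predicted = labels[idx], index = idx)
}

# batched forward over a (h, w, 3, N) tensor; returns N x K probability matrix
predict_batch <- function(model, x, batch_size = 32L) {
  n <- dim(x)[4]
  out <- matrix(0, n, model$config$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch_size - 1L)
    out[i:j, ] <- forward_cnn(model, x[, , , i:j, drop = FALSE])$probs
    i <- j + 1L
  }
  colnames(out) <- model$labels
  out
}

get_params <- function(model) {
  c(unlist(lapply(model$conv, function(p) list(p$W, p$b)),
           recursive = FALSE),
    list(model$dense$W1, model$dense$b1, model$dense$W2, model$dense$b2))
}

set_params <- function(model, params) {
  nc <- length(model$conv)
  for (i in seq_len(nc)) {
    model$conv[[i]]$W <- params[[2 * i - 1]]
    model$conv[[i]]$b <- params[[2 * i]]
  }
  model$dense$W1 <- params[[2 * nc + 1]]
  model$dense$b1 <- params[[2 * nc + 2]]
  model$dense$W2 <- params[[2 * nc + 3]]
  model$dense$b2 <- params[[2 * nc + 4]]
  model
}

grads_as_params <- function(model, gr) {
  c(unlist(lapply(gr$conv, function(p) list(p$W, p$b)), recursive = FALSE),
    list(gr$dense$W1, gr$dense$b1, gr$dense$W2, gr$dense$b2))
}
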