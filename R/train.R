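#' Augmentation configuration
#'
#' Label-preserving random transforms applied to each training image:
#' rotation, horizontal/vertical shifts, isotropic zoom, flips and
#' brightness jitter. Defaults: 20 degrees, 10% shifts, 10% zoom, both
#' flips, 10% brightness.
#'
#' @param rotation_range max absolute rotation (degrees).
#' @param width_shift,height_shift max absolute shift (fraction of size).
#' @param zoom_range max absolute zoom deviation (fraction).
#' @param horizontal_flip,vertical_flip allow random flips?
#' @param brightness_jitter max absolute brightness scaling (fraction).
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(rotation_range = 20, width_shift = 0.1,
                                height_shift = 0.1, zoom_range = 0.1,
                                horizontal_flip = TRUE, vertical_flip = TRUE,
                                brightness_jitter = 0.1) {
  vals <- c(rotation_range, width_shift, height_shift, zoom_range,
            brightness_jitter)
  if (any(vals < 0)) stop("augmentation ranges must be >= 0")
  structure(list(rotation_range = rotation_range, width_shift = width_shift,
                 height_shift = height_shift, zoom_range = zoom_range,
                 horizontal_flip = isTRUE(horizontal_flip),
                 vertical_flip = isTRUE(vertical_flip),
                 brightness_jitter = brightness_jitter),
            class = "augmentation_config")
}

#' Training configuration
#'
#' @param epochs maximum epochs (default 25).
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param early_stopping_patience epochs without validation-loss
#'   improvement before stopping (must not exceed `epochs`); default
#'   `min(10, epochs)`.
#' @param checkpoint_path optional HDF5 path; the best-validation-loss
#'   model is written there whenever it improves.
#' @param seed one integer seed driving shuffling and augmentation.
#' @param augmentation an [augmentation_config()].
#' @return a `training_config` list.
#' @export
training_config <- function(epochs = 25L, batch_size = 16L,
                            learning_rate = 1e-3,
                            early_stopping_patience = NULL,
                            checkpoint_path = NULL, seed = 1L,
                            augmentation = augmentation_config()) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (is.null(early_stopping_patience))
    early_stopping_patience <- min(10L, epochs)
  if (early_stopping_patience > epochs)
    stop("early_stopping_patience must not exceed epochs")
  stopifnot(inherits(augmentation, "augmentation_config"))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 checkpoint_path = checkpoint_path, seed = as.integer(seed),
                 augmentation = augmentation),
            class = "training_config")
}

aug_is_identity <- function(a) {
  a$rotation_range == 0 && a$width_shift == 0 && a$height_shift == 0 &&
    a$zoom_range == 0 && !a$horizontal_flip && !a$vertical_flip &&
    a$brightness_jitter == 0
}

#' Randomly augment one image tensor
#'
#' Applies one random draw from the augmentation distribution to an
#' `(h, w, 3)` array in `[0, 1]`: rotation about the centre, zoom, flips
#' and shifts composed into a single bilinear affine warp
#' (background-filled with zeros), then brightness scaling, clipped to
#' `[0, 1]`. Consumes RNG; seed management is the caller's.
#'
#' @param x `(h, w, 3)` array in `[0, 1]`.
#' @param acfg an [augmentation_config()].
#' @return augmented array, same shape.
#' @export
augment_image <- function(x, acfg) {
  h <- dim(x)[1]; w <- dim(x)[2]
  theta <- runif(1, -acfg$rotation_range, acfg$rotation_range) * pi / 180
  zoom <- 1 + runif(1, -acfg$zoom_range, acfg$zoom_range)
  fx <- if (acfg$horizontal_flip && runif(1) < 0.5) -1 else 1
  fy <- if (acfg$vertical_flip && runif(1) < 0.5) -1 else 1
  sx <- runif(1, -acfg$width_shift, acfg$width_shift) * w
  sy <- runif(1, -acfg$height_shift, acfg$height_shift) * h
  bright <- 1 + runif(1, -acfg$brightness_jitter, acfg$brightness_jitter)

  rot <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  A <- rot %*% diag(c(zoom * fx, zoom * fy))
  ctr <- c(w, h) / 2
  m <- rbind(A, ctr - as.vector(ctr %*% A) + c(sx, sy))

  eb <- EBImage::Image(aperm(x, c(2, 1, 3)), colormode = "Color")
  warped <- EBImage::affine(eb, m, filter = "bilinear",
                            output.dim = c(w, h), bg.col = 0)
  out <- aperm(EBImage::imageData(warped), c(2, 1, 3)) * bright
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * grads[[i]]
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
  }
  list(params = params, state = st)
}

stratified_holdout <- function(y, fraction) {
  idx_val <- integer(0)
  for (cl in unique(y)) {
    ids <- which(y == cl)
    if (length(ids) < 2)
      stop("class '", cl, "' has fewer than 2 images; cannot hold out ",
           "a validation split")
    n_val <- max(1L, round(fraction * length(ids)))
    if (n_val >= length(ids)) n_val <- length(ids) - 1L
    idx_val <- c(idx_val, sample(ids, n_val))
  }
  sort(idx_val)
}

#' Train the colony classifier
#'
#' Minimises mean cross-entropy with Adam over augmented mini-batches.
#' A stratified fraction of the training data is held out for validation;
#' validation loss is monitored every epoch for early stopping (after
#' `early_stopping_patience` epochs without improvement) and
#' checkpointing: the weights with the lowest validation loss seen are
#' restored into the returned model (and written to `checkpoint_path`
#' when set). Reported per-epoch training accuracy/loss are the running
#' means over the augmented batches, validation metrics are computed on
#' the clean held-out images.
#'
#' @param model an untrained (or warm) `colony_cnn`.
#' @param data a list with `x` (`(h, w, 3, N)` array in `[0, 1]`) and `y`
#'   (character labels), e.g. from [dataset_tensors()], or a
#'   `labeled_dataset` (loaded without plate detection).
#' @param tcfg a [training_config()].
#' @param validation_fraction fraction of `data` held out per class.
#' @return list with `model` (best-checkpoint weights, labels attached)
#'   and `history` (`data.frame(epoch, accuracy, loss, val_accuracy,
#'   val_loss)`, class `training_history`).
#' @export
train_model <- function(model, data, tcfg = training_config(),
                        validation_fraction = 0.2) {
  stopifnot(inherits(model, "colony_cnn"), inherits(tcfg, "training_config"))
  if (inherits(data, "labeled_dataset")) data <- dataset_tensors(data)
  labels <- sort(unique(data$y))
  if (length(labels) != model$config$n_classes)
    stop("dataset has ", length(labels), " classes but the model expects ",
         model$config$n_classes)
  model$labels <- labels
  y_idx <- match(data$y, labels)
  n <- dim(data$x)[4]
  k <- length(labels)

  run_with_seed(tcfg$seed, {
    val_ids <- stratified_holdout(data$y, validation_fraction)
    tr_ids <- setdiff(seq_len(n), val_ids)
    xv <- data$x[, , , val_ids, drop = FALSE]
    yv <- y_idx[val_ids]

    params <- get_params(model)
    st <- adam_init(params)
    use_aug <- !aug_is_identity(tcfg$augmentation)

    hist <- data.frame(epoch = integer(0), accuracy = numeric(0),
                       loss = numeric(0), val_accuracy = numeric(0),
                       val_loss = numeric(0))
    best_loss <- Inf; best_params <- params; wait <- 0L

    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample(tr_ids)
      ep_loss <- 0; ep_hits <- 0L; seen <- 0L
      i <- 1L
      while (i <= length(ord)) {
        j <- min(length(ord), i + tcfg$batch_size - 1L)
        ids <- ord[i:j]
        xb <- data$x[, , , ids, drop = FALSE]
        if (use_aug)
          for (t in seq_along(ids))
            xb[, , , t] <- augment_image(xb[, , , t], tcfg$augmentation)
        yb <- y_idx[ids]
        onehot <- matrix(0, length(ids), k)
        onehot[cbind(seq_along(ids), yb)] <- 1
        model <- set_params(model, params)
        fw <- forward_cnn(model, xb, keep_cache = TRUE)
        gr <- grads_as_params(model, backward_cnn(model, fw, onehot))
        up <- adam_step(params, gr, st, tcfg$learning_rate)
        params <- up$params; st <- up$state
        ep_loss <- ep_loss + cross_entropy(fw$probs, yb) * length(ids)
        ep_hits <- ep_hits + sum(max.col(fw$probs, "first") == yb)
        seen <- seen + length(ids)
        i <- j + 1L
      }
      model <- set_params(model, params)
      pv <- predict_batch(model, xv)
      vloss <- cross_entropy(pv, yv)
      vacc <- mean(max.col(pv, "first") == yv)
      hist <- rbind(hist, data.frame(epoch = ep, accuracy = ep_hits / seen,
                                     loss = ep_loss / seen,
                                     val_accuracy = vacc, val_loss = vloss))
      if (vloss < best_loss - 1e-9) {
        best_loss <- vloss; best_params <- params; wait <- 0L
        if (!is.null(tcfg$checkpoint_path))
          save_model(set_params(model, best_params), tcfg$checkpoint_path)
      } else {
        wait <- wait + 1L
        if (wait >= tcfg$early_stopping_patience) break
      }
    }
    model <- set_params(model, best_params)
    class(hist) <- c("training_history", class(hist))
    list(model = model, history = hist)
  })
}
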