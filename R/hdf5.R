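#' Persist a colony classifier as an HDF5 container
#'
#' The file stores every weight array under `/weights`, and the
#' architecture, input size, class labels and package version under
#' `/meta`, so a model round-trips exactly (predictions are bitwise
#' reproducible after reload).
#'
#' @param model a `colony_cnn`.
#' @param path output `.h5` path (overwritten if present).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "colony_cnn"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (file.exists(path)) unlink(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5createGroup(path, "weights")
  cfg <- model$config
  rhdf5::h5write(cfg$backbone, path, "meta/backbone")
  rhdf5::h5write(cfg$input_size, path, "meta/input_size")
  rhdf5::h5write(cfg$n_classes, path, "meta/n_classes")
  rhdf5::h5write(cfg$hidden_units, path, "meta/hidden_units")
  rhdf5::h5write(as.integer(cfg$backbone_frozen), path,
                 "meta/backbone_frozen")
  labels <- model$labels %||% character(0)
  rhdf5::h5write(labels, path, "meta/labels")
  rhdf5::h5write(as.character(utils::packageVersion("colonyid")), path,
                 "meta/format_version")
  for (i in seq_along(model$conv)) {
    rhdf5::h5write(model$conv[[i]]$W, path, sprintf("weights/conv_%02d_W", i))
    rhdf5::h5write(model$conv[[i]]$b, path, sprintf("weights/conv_%02d_b", i))
  }
  rhdf5::h5write(model$dense$W1, path, "weights/dense_W1")
  rhdf5::h5write(model$dense$b1, path, "weights/dense_b1")
  rhdf5::h5write(model$dense$W2, path, "weights/dense_W2")
  rhdf5::h5write(model$dense$b2, path, "weights/dense_b2")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a persisted colony classifier
#'
#' @param path `.h5` file written by [save_model()].
#' @param expected_classes optional class count to enforce; a mismatch is
#'   an error.
#' @return a `colony_cnn`.
#' @export
load_model <- function(path, expected_classes = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  meta <- tryCatch({
    list(backbone = as.character(rhdf5::h5read(path, "meta/backbone")),
         input_size = as.integer(rhdf5::h5read(path, "meta/input_size")),
         n_classes = as.integer(rhdf5::h5read(path, "meta/n_classes")),
         hidden_units = as.integer(rhdf5::h5read(path, "meta/hidden_units")),
         frozen = as.integer(rhdf5::h5read(path, "meta/backbone_frozen")),
         labels = as.character(rhdf5::h5read(path, "meta/labels")))
  }, error = function(e)
    stop("not a readable HDF5 model file: ", path,
         " (", conditionMessage(e), ")"))
  if (!is.null(expected_classes) && meta$n_classes != expected_classes)
    stop("model has ", meta$n_classes, " classes but ", expected_classes,
         " were expected")
  cfg <- model_config(meta$n_classes, backbone = meta$backbone,
                      input_size = meta$input_size,
                      hidden_units = meta$hidden_units,
                      backbone_frozen = meta$frozen == 1L)
  model <- build_model(cfg, seed = 0L)
  out <- tryCatch({
    for (i in seq_along(model$conv)) {
      model$conv[[i]]$W <- rhdf5::h5read(path,
                                         sprintf("weights/conv_%02d_W", i))
      model$conv[[i]]$b <- as.numeric(
        rhdf5::h5read(path, sprintf("weights/conv_%02d_b", i)))
    }
    model$dense$W1 <- rhdf5::h5read(path, "weights/dense_W1")
    model$dense$b1 <- as.numeric(rhdf5::h5read(path, "weights/dense_b1"))
    model$dense$W2 <- rhdf5::h5read(path, "weights/dense_W2")
    model$dense$b2 <- as.numeric(rhdf5::h5read(path, "weights/dense_b2"))
    model
  }, error = function(e)
    stop("corrupt model file: ", path, " (", conditionMessage(e), ")"))
  if (length(meta$labels)) out$labels <- meta$labels
  out
}
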