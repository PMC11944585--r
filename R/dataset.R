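#' Load a species-labelled image dataset
#'
#' Expects the standard training layout: one subdirectory per species under
#' `root`, each holding that species' plate photographs (JPEG/PNG). Labels
#' are the subdirectory names in sorted order, which fixes the classifier's
#' output-index mapping.
#'
#' @param root dataset root directory.
#' @param input_size `(h, w)` the classifier will ingest.
#' @return a `labeled_dataset`: labels, per-class file lists, counts.
#' @export
load_dataset <- function(root, input_size = c(64L, 64L)) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  subs <- sort(basename(list.dirs(root, recursive = FALSE)))
  if (length(subs) < 2)
    stop("dataset needs at least 2 class subdirectories, found ",
         length(subs))
  files <- lapply(subs, function(s) {
    f <- sort(list.files(file.path(root, s),
                         pattern = "\\.(png|jpe?g)$", ignore.case = TRUE))
    file.path(s, f)
  })
  names(files) <- subs
  empty <- subs[vapply(files, length, 1L) == 0]
  if (length(empty))
    stop("class subdirectory with no images: ", paste(empty, collapse = ", "))
  structure(list(root = root, labels = subs, files = files,
                 counts = vapply(files, length, 1L),
                 input_size = as.integer(input_size)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labelled dataset:", sum(x$counts), "images,",
      length(x$labels), "classes\n")
  for (l in x$labels) cat(sprintf("  %-20s %d\n", l, x$counts[[l]]))
  invisible(x)
}

#' Materialise a dataset as model-ready tensors
#'
#' Reads every image, optionally runs plate detection and crops the
#' best-fitting circle (falling back to the full frame when no circle is
#' found), resizes to the dataset's `input_size` and scales to `[0, 1]`.
#'
#' @param dataset a [load_dataset()] result.
#' @param detect run [detect_plates()] + [crop_circle()] per image?
#' @param params [hough_params()] used when `detect = TRUE`.
#' @return list with `x` (`(h, w, 3, N)` array in `[0, 1]`), `y` (character
#'   labels), `paths`, `labels` (class levels) and `n_undetected`.
#' @export
dataset_tensors <- function(dataset, detect = FALSE,
                            params = hough_params()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  paths <- unlist(dataset$files, use.names = FALSE)
  y <- rep(dataset$labels, dataset$counts)
  h <- dataset$input_size[1]; w <- dataset$input_size[2]
  x <- array(0, c(h, w, 3, length(paths)))
  n_undetected <- 0L
  for (i in seq_along(paths)) {
    fp <- file.path(dataset$root, paths[i])
    img <- tryCatch(read_rgb(fp),
                    error = function(e) stop("unreadable image file: ", fp,
                                             " (", conditionMessage(e), ")"))
    if (detect) {
      best <- select_best_circle(detect_plates(compute_edge_map(img), params),
                                 dim(img)[1:2])
      if (is.null(best)) {
        n_undetected <- n_undetected + 1L
        crop <- resize_rgb(img, h, w)
      } else {
        crop <- crop_circle(img, best, target = c(h, w))
      }
    } else {
      crop <- resize_rgb(img, h, w)
    }
    x[, , , i] <- unclass(crop) / 255
  }
  list(x = x, y = y, paths = paths, labels = dataset$labels,
       n_undetected = n_undetected)
}
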