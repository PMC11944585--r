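#' Stratified 70/30 train/test split
#'
#' Splits per class so that overall `|train| = round(0.7 * n)`: each class
#' contributes `floor(0.7 * n_c)` training images, and the remainder needed
#' to reach the overall target is assigned to the classes with the largest
#' fractional parts. Deterministic under `seed`; train and test are
#' disjoint.
#'
#' @param y character/factor label per image (or a `labeled_dataset`).
#' @param seed integer RNG seed.
#' @param train_fraction training share (default 0.7).
#' @return list with integer id vectors `train` and `test`.
#' @export
split_70_30 <- function(y, seed = 1L, train_fraction = 0.7) {
  y <- dataset_labels(y)
  n <- length(y)
  classes <- sort(unique(as.character(y)))
  counts <- table(factor(y, classes))
  if (any(counts == 0)) stop("every class needs at least 1 image")
  target <- round(train_fraction * n)
  raw <- train_fraction * as.numeric(counts)
  base <- floor(raw)
  extra <- target - sum(base)
  order_frac <- order(-(raw - base), seq_along(base))
  take <- base
  if (extra > 0) take[order_frac[seq_len(extra)]] <- base[order_frac[seq_len(extra)]] + 1
  run_with_seed(seed, {
    train <- integer(0)
    for (i in seq_along(classes)) {
      ids <- which(y == classes[i])
      train <- c(train, sample(ids, min(take[i], length(ids))))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

dataset_labels <- function(y) {
  if (inherits(y, "labeled_dataset")) rep(y$labels, y$counts)
  else as.character(y)
}

#' Stratified k-fold assignment
#'
#' Partitions ids into `k` folds whose sizes differ by at most one, keeping
#' every class spread as evenly as possible across folds (a global
#' round-robin over shuffled within-class ids). If some class has fewer
#' than `k` images the assignment degrades to the same round-robin with a
#' warning (stratification is then only approximate for that class).
#'
#' @param y labels per image (or a `labeled_dataset`).
#' @param k number of folds (default 5).
#' @param seed integer RNG seed.
#' @return a `fold_assignment`: `k`, per-image `fold` index, and
#'   `train`/`test` id lists per fold.
#' @export
make_folds <- function(y, k = 5L, seed = 1L) {
  y <- dataset_labels(y)
  n <- length(y)
  if (k > n) stop("k = ", k, " exceeds the number of images (", n, ")")
  classes <- sort(unique(y))
  small <- classes[table(factor(y, classes)) < k]
  if (length(small))
    warning("classes with fewer than ", k, " images (",
            paste(small, collapse = ", "),
            "): every-fold-test coverage is not feasible for them")
  run_with_seed(seed, {
    fold <- integer(n)
    pos <- 0L
    for (cl in classes) {
      ids <- sample(which(y == cl))
      fold[ids] <- ((pos + seq_along(ids) - 1L) %% k) + 1L
      pos <- pos + length(ids)
    }
    structure(list(
      k = as.integer(k), fold = fold,
      test = lapply(seq_len(k), function(f) which(fold == f)),
      train = lapply(seq_len(k), function(f) which(fold != f))
    ), class = "fold_assignment")
  })
}

#' Run the k-fold cross-validation protocol
#'
#' For each fold: builds a fresh model (fold-specific seed derived from
#' `tcfg$seed`), trains it on the fold's training ids and stores, for every
#' test image, the full class-probability vector and argmax label. A
#' failing run is recorded (`ok = FALSE`) without aborting the remaining
#' runs. Across the k runs every image is classified exactly once.
#'
#' @param data tensor dataset (list with `x`, `y`, optionally `paths`),
#'   e.g. from [dataset_tensors()]. Upstream, multi-circle photographs must
#'   already be reduced to their best-fitting plate crop — that is what
#'   [dataset_tensors()] with `detect = TRUE` does.
#' @param model_cfg a [model_config()].
#' @param tcfg a [training_config()].
#' @param folds a [make_folds()] result.
#' @param validation_fraction passed to [train_model()].
#' @return a `cv_result`: per-run list (`history`, `predictions`, `ok`)
#'   plus pooled `predictions` across runs
#'   (`path,true_label,predicted_label,p_<class>...,run`).
#' @export
run_cross_validation <- function(data, model_cfg, tcfg, folds,
                                 validation_fraction = 0.2) {
  stopifnot(inherits(folds, "fold_assignment"))
  labels <- sort(unique(data$y))
  runs <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    runs[[f]] <- tryCatch({
      tr <- folds$train[[f]]; te <- folds$test[[f]]
      fold_tcfg <- tcfg
      fold_tcfg$seed <- (tcfg$seed + 7919L * f) %% .Machine$integer.max
      model <- build_model(model_cfg, seed = fold_tcfg$seed)
      fit <- train_model(model,
                         list(x = data$x[, , , tr, drop = FALSE],
                              y = data$y[tr]),
                         fold_tcfg, validation_fraction)
      probs <- predict_batch(fit$model, data$x[, , , te, drop = FALSE])
      pred <- data.frame(
        path = if (!is.null(data$paths)) data$paths[te] else as.character(te),
        true_label = data$y[te],
        predicted_label = labels[max.col(probs, "first")],
        run = f)
      colnames(probs) <- paste0("p_", labels)
      pred <- cbind(pred, as.data.frame(probs))
      list(ok = TRUE, history = fit$history, predictions = pred)
    }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  }
  pooled <- do.call(rbind, lapply(runs[vapply(runs, `[[`, TRUE, "ok")],
                                  `[[`, "predictions"))
  structure(list(runs = runs, predictions = pooled, labels = labels),
            class = "cv_result")
}

#' Aggregate confusion matrix from pooled predictions
#'
#' Rows are predicted species, columns actual species. Cell `[p, a]`
#' counts images of actual class `a` predicted as `p`; summing per-run
#' matrices equals the matrix of the pooled predictions.
#'
#' @param predictions `data.frame` with `true_label` and `predicted_label`.
#' @param labels class label set (order fixes rows/columns).
#' @return integer matrix of class `confusion_matrix`.
#' @export
confusion_from_predictions <- function(predictions, labels) {
  bad <- setdiff(unique(c(predictions$true_label,
                          predictions$predicted_label)), labels)
  if (length(bad))
    stop("labels absent from the label set: ", paste(bad, collapse = ", "))
  m <- table(factor(predictions$predicted_label, labels),
             factor(predictions$true_label, labels))
  structure(unclass(m), dimnames = list(predicted = labels, actual = labels),
            class = "confusion_matrix")
}

#' Per-species metrics from one-vs-rest counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/N`, PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)` (all as percentages),
#' F1 `2*PPV*Sens/(PPV+Sens)` and MCC
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` (dimensionless).
#' Any metric with a zero denominator is returned as `NA` (undefined),
#' never coerced to 0.
#'
#' @param tp,fn,fp,tn non-negative integer counts, not all zero.
#' @param species optional label attached to the row.
#' @return one-row `data.frame(species, sensitivity, specificity,
#'   accuracy, ppv, npv, f1, mcc)`.
#' @export
metrics_from_counts <- function(tp, fn, fp, tn, species = NA_character_) {
  cts <- c(tp, fn, fp, tn)
  if (any(cts < 0)) stop("counts must be non-negative")
  if (sum(cts) == 0) stop("at least one count must be positive")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  acc <- (tp + tn) / sum(cts)
  ppv <- div(tp, tp + fp)
  npv <- div(tn, tn + fn)
  f1 <- if (!is.na(ppv) && !is.na(sens) && ppv + sens > 0)
    2 * ppv * sens / (ppv + sens) else NA_real_
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else NA_real_
  data.frame(species = species, sensitivity = 100 * sens,
             specificity = 100 * spec, accuracy = 100 * acc,
             ppv = 100 * ppv, npv = 100 * npv, f1 = f1, mcc = mcc,
             stringsAsFactors = FALSE)
}

#' One-vs-rest binarization of a confusion matrix
#'
#' For the given species: TP is its diagonal cell, FN the rest of its
#' actual column, FP the rest of its predicted row, TN everything else;
#' the four counts always sum to the matrix grand total.
#'
#' @param x a `confusion_matrix` (rows predicted, columns actual) or a
#'   predictions `data.frame` (converted internally).
#' @param species species label.
#' @param labels label set, required when `x` is a predictions frame.
#' @return named integer vector `c(tp, fn, fp, tn)`.
#' @export
one_vs_rest_binarize <- function(x, species, labels = NULL) {
  if (is.data.frame(x)) {
    if (is.null(labels)) labels <- sort(unique(x$true_label))
    x <- confusion_from_predictions(x, labels)
  }
  m <- unclass(x)
  if (!species %in% rownames(m)) stop("unknown species: ", species)
  tp <- m[species, species]
  fn <- sum(m[, species]) - tp
  fp <- sum(m[species, ]) - tp
  tn <- sum(m) - tp - fn - fp
  c(tp = as.integer(tp), fn = as.integer(fn), fp = as.integer(fp),
    tn = as.integer(tn))
}

#' One-vs-rest ROC curve and AUC for one species
#'
#' Positives are test images of the species, negatives all others; the
#' species' softmax probability is swept over thresholds. Points run from
#' (0, 0) to (1, 1); AUC is the trapezoidal area, which equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative (ties counting one half).
#'
#' @param predictions pooled predictions with `true_label` and
#'   `p_<species>` probability columns.
#' @param species species label.
#' @return a `roc_curve`: `species`, `fpr`, `tpr`, `auc`. When the species
#'   is absent from the test data the curve is undefined: `auc` is `NA`
#'   and a warning is raised.
#' @export
roc_ovr <- function(predictions, species) {
  col <- paste0("p_", species)
  if (!col %in% names(predictions))
    stop("no probability column for species: ", species)
  pos <- predictions$true_label == species
  if (!any(pos) || all(pos)) {
    warning("species '", species,
            "' lacks positives or negatives in the test data; ",
            "ROC curve undefined")
    return(structure(list(species = species, fpr = NA_real_,
                          tpr = NA_real_, auc = NA_real_),
                     class = "roc_curve"))
  }
  sc <- predictions[[col]]
  o <- order(-sc)
  sc <- sc[o]; pos <- pos[o]
  # step through tied-score groups
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(species = species, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarise per-species metric rows with an average line
#'
#' Appends an `Average results` row holding the unweighted arithmetic mean
#' of each metric column over species, and rounds every value half-up to
#' two decimals (percentages and F1/MCC alike). Undefined (`NA`) entries
#' are skipped in the averages with a warning.
#'
#' @param rows `data.frame` of [metrics_from_counts()] rows.
#' @return rounded `data.frame` with the extra average row.
#' @export
summarize_table <- function(rows) {
  if (nrow(rows) < 1) stop("need at least one metric row")
  num_cols <- c("sensitivity", "specificity", "accuracy", "ppv", "npv",
                "f1", "mcc")
  if (anyNA(rows[num_cols]))
    warning("undefined metric entries are skipped in the averages")
  avg <- vapply(rows[num_cols], function(v) mean(v, na.rm = TRUE), 0)
  out <- rbind(rows[c("species", num_cols)],
               data.frame(species = "Average results", t(avg)))
  out[num_cols] <- lapply(out[num_cols], round_half_up, digits = 2)
  rownames(out) <- NULL
  out
}

#' Reconstruct integer one-vs-rest counts from a printed metric row
#'
#' Searches non-negative integers `(TP, FN, FP, TN)` whose seven metrics
#' round (half-up, 2 decimals) to the printed values. Used to check a
#' published metrics table for internal consistency and to recover exact
#' counts behind rounded percentages.
#'
#' @param row one-row `data.frame` with `sensitivity, specificity,
#'   accuracy, ppv, npv, f1, mcc` (percent / dimensionless as printed).
#' @param max_positives upper bound on `TP + FN` searched.
#' @param max_total upper bound on the grand total.
#' @return named vector `c(tp, fn, fp, tn)` or `NULL` when no counts fit.
#' @export
reconstruct_counts <- function(row, max_positives = 150L, max_total = 600L) {
  match2 <- function(value, printed) {
    !is.na(value) && abs(round_half_up(value, 2) - printed) < 1e-9
  }
  for (p in 1:max_positives) {
    tps <- which(abs(100 * (0:p) / p - row$sensitivity) <= 0.005 + 1e-9) - 1L
    for (tp in tps) {
      fn <- p - tp
      # fp interval from the rounding window of ppv = 100 tp / (tp + fp)
      fps <- if (tp == 0) {
        if (row$ppv == 0) 0:max_total else next
      } else {
        lo <- tp * (100 - row$ppv - 0.005) / (row$ppv + 0.005)
        hi <- tp * (100 - row$ppv + 0.005) / max(row$ppv - 0.005, 1e-9)
        if (ceiling(hi) < 0) next
        max(0, floor(lo)):min(max_total, ceiling(hi))
      }
      for (fp in fps) {
        if (!match2(if (tp + fp > 0) 100 * tp / (tp + fp) else NA, row$ppv))
          next
        # tn interval from the rounding window of spec = 100 tn / (tn + fp)
        tns <- if (fp == 0) {
          if (row$specificity == 100) 0:max_total else next
        } else if (row$specificity >= 100) {
          next  # impossible with fp > 0
        } else {
          s_lo <- row$specificity - 0.005
          s_hi <- row$specificity + 0.005
          max(0, floor(fp * s_lo / (100 - s_lo))):
            min(max_total, ceiling(fp * s_hi / (100 - s_hi)))
        }
        for (tn in tns) {
          if (tp + fn + fp + tn > max_total) next
          m <- metrics_from_counts(tp, fn, fp, tn)
          if (match2(m$specificity, row$specificity) &&
              match2(m$accuracy, row$accuracy) &&
              match2(m$npv, row$npv) &&
              match2(m$f1, row$f1) &&
              match2(m$mcc, row$mcc))
            return(c(tp = tp, fn = fn, fp = fp, tn = tn))
        }
      }
    }
  }
  NULL
}
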