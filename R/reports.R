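#' Render the evaluation report figures and tables
#'
#' Writes four artefacts into `out_dir`:
#' * `training_curves.png` — four panels (accuracy, loss, validation
#'   accuracy, validation loss) with one coloured line per run;
#' * `confusion_heatmap.png` — column-normalised heatmap (darker = higher
#'   percentage), each cell annotated `count (pct%)`, rows predicted and
#'   columns actual species;
#' * `roc_curves.png` — one-vs-rest ROC per species with the AUC in the
#'   legend and the chance diagonal dashed;
#' * `metrics.csv` — the per-species metric table with its average row.
#'
#' @param histories list of `training_history` data.frames (one per run).
#' @param confusion a `confusion_matrix`.
#' @param table summarised metric table from [summarize_table()].
#' @param rocs list of `roc_curve`s.
#' @param out_dir output directory (created if missing).
#' @return named character vector of the file paths written.
#' @export
render_reports <- function(histories, confusion, table, rocs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c(curves = file.path(out_dir, "training_curves.png"),
             heatmap = file.path(out_dir, "confusion_heatmap.png"),
             roc = file.path(out_dir, "roc_curves.png"),
             metrics = file.path(out_dir, "metrics.csv"))

  # training curves
  long <- do.call(rbind, lapply(seq_along(histories), function(i) {
    h <- as.data.frame(histories[[i]])
    do.call(rbind, lapply(c("accuracy", "loss", "val_accuracy", "val_loss"),
                          function(mt) data.frame(run = factor(i),
                                                  epoch = h$epoch,
                                                  metric = mt,
                                                  value = h[[mt]])))
  }))
  long$metric <- factor(long$metric,
                        c("accuracy", "loss", "val_accuracy", "val_loss"))
  p1 <- ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                           colour = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = "run",
                  title = "Training metrics per cross-validation run") +
    ggplot2::theme_bw()
  ggplot2::ggsave(paths[["curves"]], p1, width = 8, height = 6, dpi = 120)

  # confusion heatmap, column-normalised
  m <- unclass(confusion)
  cs <- colSums(m)
  pct <- sweep(m, 2, ifelse(cs == 0, 1, cs), "/") * 100
  df <- data.frame(predicted = factor(rep(rownames(m), ncol(m)),
                                      rev(rownames(m))),
                   actual = factor(rep(colnames(m), each = nrow(m)),
                                   colnames(m)),
                   count = as.vector(m), pct = as.vector(pct))
  df$label <- sprintf("%d (%.1f%%)", df$count, df$pct)
  p2 <- ggplot2::ggplot(df, ggplot2::aes(.data$actual, .data$predicted,
                                         fill = .data$pct)) +
    ggplot2::geom_tile(colour = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
                                 limits = c(0, 100), name = "% of actual") +
    ggplot2::labs(x = "actual species", y = "predicted species",
                  title = "Aggregate confusion matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  ggplot2::ggsave(paths[["heatmap"]], p2, width = 8, height = 7, dpi = 120)

  # ROC curves
  ok <- Filter(function(r) !is.na(r$auc), rocs)
  rdf <- do.call(rbind, lapply(ok, function(r)
    data.frame(species = sprintf("%s (AUC = %.2f)", r$species, r$auc),
               fpr = r$fpr, tpr = r$tpr)))
  p3 <- ggplot2::ggplot(rdf, ggplot2::aes(.data$fpr, .data$tpr,
                                          colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  colour = NULL, title = "One-vs-rest ROC curves") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "right")
  ggplot2::ggsave(paths[["roc"]], p3, width = 8, height = 5.5, dpi = 120)

  write.csv(table, paths[["metrics"]], row.names = FALSE)
  paths
}

#' @importFrom ggplot2 .data
NULL
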