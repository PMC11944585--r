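test_that("the 70/30 split is stratified, disjoint and reproducible", {
  y <- rep(c("a", "b", "c", "d"), each = 30)
  sp <- split_70_30(y, seed = 5)
  expect_length(sp$train, 84)
  expect_length(sp$test, 36)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  tab <- table(y[sp$train])
  expect_true(all(tab == 21))
  expect_identical(split_70_30(y, seed = 5), sp)
  expect_false(identical(split_70_30(y, seed = 6), sp))

  # unbalanced classes still hit the overall round(0.7 n) target
  y2 <- rep(c("a", "b", "c"), c(11, 7, 5))
  sp2 <- split_70_30(y2, seed = 1)
  expect_length(sp2$train, round(0.7 * 23))
})

test_that("k-fold partitions are balanced, stratified and exhaustive", {
  y269 <- rep(paste0("s", 1:10), c(27, 27, 27, 27, 27, 27, 27, 27, 27, 26))
  f <- make_folds(y269, k = 5, seed = 2)
  sizes <- sort(vapply(f$test, length, 1L))
  expect_equal(sizes, c(53L, 54L, 54L, 54L, 54L))
  expect_setequal(unlist(f$test), seq_along(y269))
  for (i in 1:5) {
    expect_setequal(c(f$train[[i]], f$test[[i]]), seq_along(y269))
    # stratified: every class appears in every fold's test set
    expect_setequal(unique(y269[f$test[[i]]]), unique(y269))
  }

  f10 <- make_folds(rep(c("a", "b"), 5), k = 5, seed = 1)
  expect_true(all(vapply(f10$test, length, 1L) == 2))

  expect_error(make_folds(rep("a", 3), k = 5), "exceeds")
  expect_warning(make_folds(rep(c("a", "b"), c(3, 17)), k = 5, seed = 1),
                 "fewer than")
})

test_that("confusion matrices count predicted-by-actual and pool additively", {
  labs <- c("A", "B")
  perfect <- data.frame(true_label = c("A", "A", "B"),
                        predicted_label = c("A", "A", "B"))
  m <- confusion_from_predictions(perfect, labs)
  expect_equal(as.vector(unclass(m)), c(2L, 0L, 0L, 1L))

  three <- data.frame(true_label = c("A", "A", "B"),
                      predicted_label = c("A", "B", "B"))
  m3 <- confusion_from_predictions(three, labs)
  expect_equal(unclass(m3)["A", "A"], 1L)
  expect_equal(unclass(m3)["B", "A"], 1L)
  expect_equal(unclass(m3)["B", "B"], 1L)
  # column sums are the per-class test counts
  expect_equal(as.vector(colSums(unclass(m3))), c(2L, 1L))

  expect_error(confusion_from_predictions(
    data.frame(true_label = "Z", predicted_label = "A"), labs), "absent")

  # pooling: per-run matrices sum to the pooled matrix
  run1 <- three; run2 <- perfect
  pooled <- confusion_from_predictions(rbind(run1, run2), labs)
  expect_equal(unclass(confusion_from_predictions(run1, labs)) +
                 unclass(confusion_from_predictions(run2, labs)),
               unclass(pooled))
})

test_that("metric formulas match hand-computed reference counts", {
  # counts consistent with a published Penicillium chrysogenum row
  m <- metrics_from_counts(5, 0, 1, 203)
  expect_equal(colonyid:::round_half_up(m$sensitivity), 100.00)
  expect_equal(colonyid:::round_half_up(m$specificity), 99.51)
  expect_equal(colonyid:::round_half_up(m$accuracy), 99.52)
  expect_equal(colonyid:::round_half_up(m$ppv), 83.33)
  expect_equal(colonyid:::round_half_up(m$npv), 100.00)
  expect_equal(colonyid:::round_half_up(m$f1), 0.91)
  expect_equal(colonyid:::round_half_up(m$mcc), 0.91)

  perfect <- metrics_from_counts(10, 0, 0, 90)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mcc, 1)

  # zero denominators flagged as undefined, not zero
  none <- metrics_from_counts(0, 0, 3, 97)
  expect_true(is.na(none$sensitivity))   # TP + FN = 0
  expect_equal(none$ppv, 0)              # 0 / 3 is defined
  expect_false(is.na(none$specificity))
  nopred <- metrics_from_counts(0, 5, 0, 95)
  expect_true(is.na(nopred$ppv))         # TP + FP = 0
  expect_true(is.na(nopred$f1))
  expect_true(is.na(nopred$mcc))

  expect_error(metrics_from_counts(-1, 0, 0, 5), "non-negative")
  expect_error(metrics_from_counts(0, 0, 0, 0), "positive")
})

test_that("metrics and binarization agree with a per-item counting oracle", {
  set.seed(314)
  for (rep in 1:200) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(k * k, 3), k, k,
                dimnames = list(paste0("c", 1:k), paste0("c", 1:k)))
    if (sum(m) == 0) next
    cm <- structure(m, class = "confusion_matrix")
    for (sp in rownames(m)) {
      got <- one_vs_rest_binarize(cm, sp)
      want <- ovr_counts_oracle(m, sp)
      expect_identical(got, want)
      expect_equal(sum(got), sum(m))  # conservation
      if (sum(got[c("tp", "fn")]) > 0 && sum(got[c("tp", "fp")]) > 0) {
        mm <- metrics_from_counts(got["tp"], got["fn"], got["fp"],
                                  got["tn"])
        expect_equal(mm$sensitivity,
                     100 * got["tp"] / (got["tp"] + got["fn"]),
                     ignore_attr = TRUE)
        expect_equal(mm$accuracy, 100 * (got["tp"] + got["tn"]) / sum(got),
                     ignore_attr = TRUE)
      }
    }
  }
  expect_error(one_vs_rest_binarize(
    structure(matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))),
              class = "confusion_matrix"), "zz"), "unknown species")
})

test_that("the worked 2x2 binarization example counts out by hand", {
  m <- structure(matrix(c(3, 2, 1, 4), 2, 2,
                        dimnames = list(c("c0", "c1"), c("c0", "c1"))),
                 class = "confusion_matrix")
  got <- one_vs_rest_binarize(m, "c0")
  expect_equal(got, c(tp = 3L, fn = 2L, fp = 1L, tn = 4L))
})

test_that("MCC is swap-symmetric and F1 ignores true negatives", {
  set.seed(99)
  for (i in 1:50) {
    ct <- rpois(4, 8) + 1
    a <- metrics_from_counts(ct[1], ct[2], ct[3], ct[4])
    sw <- metrics_from_counts(ct[4], ct[3], ct[2], ct[1])  # TP<->TN, FP<->FN
    expect_equal(a$mcc, sw$mcc)
    b <- metrics_from_counts(ct[1], ct[2], ct[3], ct[4] + 50)
    expect_equal(a$f1, b$f1)
  }
})

test_that("ROC sweeps match exhaustive pair counting and handle ties", {
  mk <- function(pos, neg) {
    data.frame(true_label = rep(c("X", "other"), c(length(pos), length(neg))),
               p_X = c(pos, neg))
  }
  expect_equal(roc_ovr(mk(c(0.9, 0.8), c(0.4, 0.2)), "X")$auc, 1.0)
  expect_equal(roc_ovr(mk(c(0.9, 0.4), c(0.8, 0.2)), "X")$auc, 0.75)
  expect_equal(roc_ovr(mk(rep(0.5, 4), rep(0.5, 6)), "X")$auc, 0.5)

  set.seed(2718)
  for (i in 1:100) {
    n_pos <- sample(1:25, 1); n_neg <- sample(1:25, 1)
    pos <- round(runif(n_pos), sample(1:3, 1))  # rounding induces ties
    neg <- round(runif(n_neg), sample(1:3, 1))
    r <- roc_ovr(mk(pos, neg), "X")
    expect_equal(r$auc, mw_auc_oracle(pos, neg), tolerance = 1e-12)
    # monotone staircase from (0,0) to (1,1)
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  }

  skip_if_not_installed("pROC")
  set.seed(11)
  pos <- runif(20); neg <- runif(30)
  r <- roc_ovr(mk(pos, neg), "X")
  ref <- suppressMessages(pROC::auc(
    rep(c(1, 0), c(20, 30)), c(pos, neg), direction = "<"))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)

  expect_warning(out <- roc_ovr(mk(numeric(0), c(0.4, 0.2)), "X"),
                 "undefined")
  expect_true(is.na(out$auc))
  expect_error(roc_ovr(data.frame(true_label = "X"), "X"),
               "no probability column")
})

test_that("summary tables append the unweighted average row and round half-up", {
  rows <- do.call(rbind, list(
    metrics_from_counts(5, 0, 1, 203, species = "a"),
    metrics_from_counts(4, 1, 1, 203, species = "b")))
  tab <- summarize_table(rows)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$species[3], "Average results")
  expect_equal(tab$sensitivity[3],
               colonyid:::round_half_up(mean(rows$sensitivity)))

  single <- summarize_table(metrics_from_counts(5, 0, 1, 203,
                                                species = "solo"))
  expect_equal(single$sensitivity[1], single$sensitivity[2])

  # half-up rounding, not banker's
  expect_equal(colonyid:::round_half_up(0.005, 2), 0.01)
  expect_equal(colonyid:::round_half_up(65.285, 2), 65.29)
  expect_equal(colonyid:::round_half_up(-0.005, 2), -0.01)

  expect_warning(summarize_table(metrics_from_counts(0, 0, 1, 9,
                                                     species = "u")),
                 "skipped")
})

test_that("cross-validation classifies every image exactly once and pools cleanly", {
  toy <- toy_tensors(k = 3, n_per = 8, size = 32, seed = 5)
  folds <- make_folds(toy$y, k = 3, seed = 4)
  cv <- run_cross_validation(toy, model_config(3, input_size = c(32L, 32L)),
                             training_config(epochs = 3, seed = 4), folds)
  expect_length(cv$runs, 3)
  expect_true(all(vapply(cv$runs, `[[`, TRUE, "ok")))
  expect_equal(nrow(cv$predictions), 24)
  expect_setequal(cv$predictions$path, as.character(1:24))
  # probability vectors are complete distributions
  pcols <- paste0("p_", sort(unique(toy$y)))
  expect_true(all(pcols %in% names(cv$predictions)))
  expect_equal(rowSums(cv$predictions[pcols]), rep(1, 24),
               tolerance = 1e-6, ignore_attr = TRUE)
  conf <- confusion_from_predictions(cv$predictions, cv$labels)
  expect_equal(sum(unclass(conf)), 24)
})

test_that("reconstructed integer counts reproduce printed metric rows", {
  rows <- reference_metric_rows()
  pc <- rows[rows$species == "Penicillium chrysogenum", ]
  ct <- reconstruct_counts(pc)
  expect_false(is.null(ct))
  m <- metrics_from_counts(ct["tp"], ct["fn"], ct["fp"], ct["tn"])
  expect_equal(colonyid:::round_half_up(m$mcc), pc$mcc)
  expect_equal(colonyid:::round_half_up(m$sensitivity), pc$sensitivity)
})
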