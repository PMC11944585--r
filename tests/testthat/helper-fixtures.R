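# Shared fixtures, built lazily in code and memoised for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small on-disk dataset: 2 species x 4 images on a 192 px canvas
tiny_dataset_dir <- function() {
  fixture("tiny_dataset", {
    dir <- file.path(tempdir(), "tiny_plates")
    unlink(dir, recursive = TRUE)
    profs <- make_profile_set(2, seed = 3)
    generate_dataset(profs, 4, dir, seed = 3, canvas = c(192L, 192L))
    dir
  })
}

# in-memory separable colour-blob tensors (no rendering, fast)
toy_tensors <- function(k = 2, n_per = 10, size = 32, noise = 0.1,
                        seed = 9) {
  key <- paste("toy", k, n_per, size, noise, seed, sep = "_")
  fixture(key, {
    set.seed(seed)
    cols <- matrix(runif(k * 3, 0.1, 0.9), k, 3)
    x <- array(0, c(size, size, 3, k * n_per))
    y <- character(k * n_per)
    i <- 0
    for (cl in seq_len(k)) for (j in seq_len(n_per)) {
      i <- i + 1
      for (ch in 1:3)
        x[, , ch, i] <- pmin(1, pmax(0, cols[cl, ch] +
                                       rnorm(size^2, 0, noise)))
      y[i] <- sprintf("sp%02d", cl)
    }
    list(x = x, y = y)
  })
}

# one rendered plate with known geometry, reused across detection tests
demo_plate <- function() {
  fixture("demo_plate", {
    profs <- make_profile_set(4, seed = 7)
    sp <- plate_spec(c(250, 260), 140, "dark", noise_sd = 5)
    c(render_plate(profs[[1]], sp, seed = 11), list(spec = sp,
                                                    profile = profs[[1]]))
  })
}

# the published per-species reference metric table (percent / dimensionless)
reference_metric_rows <- function() {
  read.csv(system.file("extdata", "reference_metrics.csv",
                       package = "colonyid"), check.names = FALSE)
}

# brute-force per-item metrics oracle: expand a confusion matrix into
# (predicted, actual) items and count the four one-vs-rest outcomes directly
ovr_counts_oracle <- function(m, species) {
  labs <- rownames(m)
  pred <- rep(rep(labs, ncol(m)), as.vector(m))
  act <- rep(rep(labs, each = nrow(m)), as.vector(m))
  c(tp = sum(pred == species & act == species),
    fn = sum(pred != species & act == species),
    fp = sum(pred == species & act != species),
    tn = sum(pred != species & act != species))
}

# exhaustive Mann-Whitney AUC oracle over all positive-negative pairs
mw_auc_oracle <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}
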