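test_that("metrics follow Se = TP/(TP+FN), Sp = TP/(TP+FP), harmonic F", {
  m <- metrics_from_counts(confusion_counts(TP = 3, FP = 1, FN = 2))
  expect_equal(m$Se, 0.6)
  expect_equal(m$Sp, 0.75)
  expect_equal(m$F, 2 * 0.45 / 1.35)
  # Se = Sp = x -> F = x (harmonic-mean identity)
  for (x in c(0.2, 0.5, 0.9)) {
    mm <- metrics_from_counts(confusion_counts(TP = 100 * x,
                                               FP = 100 * (1 - x),
                                               FN = 100 * (1 - x)))
    expect_equal(mm$F, x)
  }
  # degenerate denominators -> NA; Se = Sp = 0 -> F = 0
  expect_true(is.na(metrics_from_counts(confusion_counts(0, 0, 5))$Sp))
  expect_true(is.na(metrics_from_counts(confusion_counts(0, 5, 0))$Se))
  expect_equal(metrics_from_counts(confusion_counts(0, 5, 5))$F, 0)
  # F lies between Se and Sp
  set.seed(3)
  for (i in 1:20) {
    cc <- confusion_counts(sample(1:50, 1), sample(1:50, 1), sample(1:50, 1))
    m <- metrics_from_counts(cc)
    expect_true(m$F >= min(m$Se, m$Sp) - 1e-12 &&
                  m$F <= max(m$Se, m$Sp) + 1e-12)
  }
})

test_that("roc_score matches pair counting and is monotone-invariant", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(roc_score(c(4, 3, 2, 1), y), 1)
  expect_equal(roc_score(c(1, 2, 3, 4), y), 0)
  expect_equal(roc_score(c(4, 2, 3, 1), y), 0.75)  # one inverted pair of 4
  set.seed(11)
  for (i in 1:10) {
    yy <- stats::runif(30) < 0.5
    if (length(unique(yy)) < 2) next
    s <- stats::rnorm(30)
    expect_equal(roc_score(s, yy), auc_oracle(s, yy))
    # strictly monotone transforms leave the AUC unchanged
    expect_equal(roc_score(exp(2 * s) + 5, yy), roc_score(s, yy))
  }
  expect_error(roc_score(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

make_fm <- function(X, y) {
  structure(list(X = X, y = y,
                 index = data.frame(dim = seq_len(ncol(X)), feature = "f",
                                    position = seq_len(ncol(X)))),
            class = "feature_matrix")
}

test_that("cross_validate separates signal and stays at chance on noise", {
  set.seed(19)
  n <- 80
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- matrix(stats::runif(n * 12), n)
  X[, 1:2] <- (as.numeric(y)[row(X[, 1:2])] * 0.8 +
                 stats::runif(n * 2) * 0.2)
  fm <- make_fm(X, y)
  for (clf in c("svm", "knn")) {
    rep_sig <- cross_validate(fm, subset = 1:2, classifier = clf,
                              folds = 5, seed = 2)
    expect_true(all(c(rep_sig$Se, rep_sig$Sp, rep_sig$ROC) >= 0.95))
    # informative subset beats the all-dims model on noisy data
    rep_all <- cross_validate(fm, classifier = clf, folds = 5, seed = 2)
    expect_gte(rep_sig$F, rep_all$F - 1e-9)
  }
  counts <- cross_validate(fm, subset = 1:2, folds = 5, seed = 2)$counts
  expect_identical(counts$TP + counts$FP + counts$FN + counts$TN, 80L)
})

test_that("shuffled labels center the CV ROC distribution at 0.5", {
  set.seed(23)
  n <- 60
  X <- matrix(stats::runif(n * 6), n)
  rocs <- replicate(100, {
    y <- sample(rep(c(TRUE, FALSE), each = n / 2))
    cross_validate(make_fm(X, y), classifier = "knn", folds = 3,
                   seed = 1)$ROC
  })
  expect_lt(abs(mean(rocs) - 0.5), 0.03)
})

test_that("feature_ratio computes Table-style percentages", {
  fm <- build_matrix(tiny_set(4), default_scales())
  # subset wholly from one feature
  r <- feature_ratio(dims_for_feature(fm, "z_dna"), fm)
  expect_equal(unname(r["z_dna"]), 100)
  expect_equal(sum(r), 100, tolerance = 1e-9)
  expect_true(all(r[names(r) != "z_dna"] == 0))
  # 2 dims from feature 1, 1 from feature 2, 1 from feature 3
  sub <- c(1L, 2L, 252L, 503L)
  r2 <- feature_ratio(sub, fm)
  expect_equal(unname(r2[c("a_philicity", "b_dna_twist", "bendability")]),
               c(50, 25, 25))
  expect_equal(sum(r2), 100, tolerance = 1e-9)
  # the full dimension set splits uniformly across the 13 features
  r3 <- feature_ratio(seq_len(ncol(fm$X)), fm)
  expect_equal(unname(r3), rep(100 / 13, 13), tolerance = 1e-9)
  expect_error(feature_ratio(integer(0), fm), "empty")
})

test_that("correlate_features is symmetric with unit diagonal", {
  set.seed(29)
  seqs <- replicate(30, paste(sample(c("A","C","G","T"), 251, TRUE),
                              collapse = ""))
  sc <- toy_scale_16()
  neg <- property_scale("neg16", -sc$values)
  C <- correlate_features(seqs, list(sc, neg))
  expect_equal(unname(diag(C)), c(1, 1))
  expect_equal(C[1, 2], -1)             # a scale and its negation
  expect_equal(C, t(C))
  # two independent random scales stay weakly correlated
  s1 <- property_scale("r1", stats::setNames(stats::rnorm(16),
                                             names(sc$values)))
  s2 <- property_scale("r2", stats::setNames(stats::rnorm(16),
                                             names(sc$values)))
  C2 <- correlate_features(seqs, list(s1, s2))
  expect_lt(abs(C2[1, 2]), 0.3)
  # feature_matrix route agrees with the sequence route
  fmC <- correlate_features(build_matrix(labeled_sequence_set(
    stats::setNames(seqs, paste0("s", seq_along(seqs))),
    rep(c(TRUE, FALSE), 15)), list(sc, neg)))
  expect_equal(unname(fmC), unname(C), tolerance = 1e-9)
})

test_that("match_tss applies the 500-bp one-to-one nearest-first rule", {
  ann <- data.frame(chrom = "chr1", pos = c(1000, 5000), strand = "+",
                    id = c("a", "b"))
  # boundary: exactly 500 is a hit, 501 is not
  expect_identical(match_tss(data.frame(chrom = "chr1", pos = 1500), ann)$TP, 1L)
  cc <- match_tss(data.frame(chrom = "chr1", pos = 1501), ann)
  expect_identical(c(cc$TP, cc$FP, cc$FN), c(0L, 1L, 2L))
  # two predictions near one TSS: one TP, one FP
  cc2 <- match_tss(c(990, 1010), data.frame(chrom = "*", pos = 1000))
  expect_identical(c(cc2$TP, cc2$FP, cc2$FN), c(1L, 1L, 0L))
  # nearest-first: the closer prediction claims the TSS
  cc3 <- match_tss(c(1400, 1100), data.frame(chrom = "*", pos = c(1000, 1450)))
  expect_identical(c(cc3$TP, cc3$FP, cc3$FN), c(2L, 0L, 0L))
  # chromosome-aware when both sides carry chrom
  cc4 <- match_tss(data.frame(chrom = "chr2", pos = 1000), ann)
  expect_identical(cc4$TP, 0L)
  expect_error(match_tss(1, 1, tol = -1), "tol")
})

test_that("write_metrics emits JSON and TSV", {
  fm <- make_fm(matrix(stats::runif(40 * 4), 40),
                rep(c(TRUE, FALSE), each = 20))
  rep <- cross_validate(fm, classifier = "knn", folds = 4, seed = 1)
  path <- withr::local_tempfile()
  write_metrics(rep, path)
  j <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(j$ROC, rep$ROC, tolerance = 1e-12)
  expect_identical(j$folds, 4L)
  expect_true(file.exists(paste0(path, ".tsv")))
})
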