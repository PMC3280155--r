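# Xd column realizing a 2-bin x 2-class contingency table
col_from_table <- function(tab, y) {
  # tab[bin, class]: class order (TRUE, FALSE)
  col <- integer(length(y))
  col[y] <- rep(seq_len(nrow(tab)), tab[, 1])
  col[!y] <- rep(seq_len(nrow(tab)), tab[, 2])
  col
}

test_that("MDL discretization finds the supervised cut, or collapses", {
  y8 <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  d <- discretize_mdl(matrix(1:8, ncol = 1), y8)
  expect_equal(d$cuts[[1]], 4.5)
  expect_identical(unname(d$Xd[, 1]), rep(1:2, each = 4))

  # alternating labels: no cut passes the MDL test -> single bin
  d2 <- discretize_mdl(matrix(1:8, ncol = 1), rep(c(TRUE, FALSE), 4))
  expect_length(d2$cuts[[1]], 0)
  expect_identical(unique(d2$Xd[, 1]), 1L)

  # constant column -> single bin
  d3 <- discretize_mdl(matrix(rep(2, 8), ncol = 1), y8)
  expect_length(d3$cuts[[1]], 0)

  expect_error(discretize_mdl(matrix(1, 1, 1), TRUE), "2 samples")
})

test_that("MDL top-level cut matches the exhaustive-cut oracle", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(8:16, 1)
    x <- round(stats::runif(n), 2)
    y <- stats::runif(n) < 0.5
    if (length(unique(y)) < 2) next
    oracle <- mdl_cut_oracle(x, y)
    cuts <- discretize_mdl(matrix(x, ncol = 1), y)$cuts[[1]]
    if (length(oracle) == 0) {
      expect_length(cuts, 0)
    } else {
      expect_true(oracle %in% cuts,
                  label = sprintf("case %d: oracle cut %.3f in {%s}",
                                  i, oracle, toString(cuts)))
    }
  }
})

test_that("information gain follows the entropy arithmetic", {
  y <- rep(c(TRUE, FALSE), each = 10)
  perfect <- col_from_table(rbind(c(10, 0), c(0, 10)), y)
  skewed <- col_from_table(rbind(c(8, 2), c(2, 8)), y)
  Xd <- cbind(perfect, skewed, constant = 1L)
  sc <- ig_scores(Xd, y)$scores
  expect_equal(unname(sc[1]), 1)                     # dim == balanced label
  h08 <- -(0.8 * log2(0.8) + 0.2 * log2(0.2))
  expect_equal(unname(sc[2]), 1 - h08)               # = 0.2780719 bits
  expect_equal(unname(sc[3]), 0)
})

test_that("chi-square matches direct contingency arithmetic", {
  y <- rep(c(TRUE, FALSE), each = 10)
  Xd <- cbind(col_from_table(rbind(c(10, 0), c(0, 10)), y),
              col_from_table(rbind(c(8, 2), c(2, 8)), y),
              1L)
  sc <- chi2_scores(Xd, y)$scores
  expect_equal(unname(sc), c(20, 7.2, 0))
  # independent dimension scores ~ 0
  yb <- rep(c(TRUE, FALSE), 10)
  ind <- rep(1:2, each = 10)
  expect_equal(unname(chi2_scores(cbind(ind), yb)$scores), 0)
})

test_that("IG and CHI rank equal-margin 2x2 tables identically", {
  y <- rep(c(TRUE, FALSE), each = 20)
  as_col <- function(a) col_from_table(rbind(c(a, 20 - a), c(20 - a, a)), y)
  Xd <- sapply(11:20, as_col)
  ig <- ig_scores(Xd, y)$scores
  chi <- chi2_scores(Xd, y)$scores
  expect_identical(order(ig), order(chi))
  expect_true(all(diff(ig) > 0) && all(diff(chi) > 0))  # monotone in assoc.
})

test_that("ReliefF reproduces the hand-worked 4-instance update", {
  X <- rbind(c(0.0, 0.0), c(0.1, 1.0), c(1.0, 0.1), c(0.9, 1.0))
  y <- c(TRUE, TRUE, FALSE, FALSE)
  sc <- relieff_scores(X, y, k_neighbors = 1)
  expect_equal(unname(sc$scores), c(0.8, -0.9))
})

test_that("ReliefF equals the brute-force oracle for n <= 20", {
  set.seed(77)
  for (k in c(1, 3, 5)) {
    n <- 18
    X <- cbind(matrix(stats::runif(n * 3), n), constant = 0.5)
    y <- rep(c(TRUE, FALSE), each = n / 2)
    sc <- relieff_scores(X, y, k_neighbors = k)
    expect_equal(unname(sc$scores), unname(relieff_oracle(X, y, k)),
                 tolerance = 1e-12)
    expect_equal(unname(sc$scores[4]), 0)   # constant dim has weight 0
  }
})

test_that("ReliefF separates signal from noise and samples reproducibly", {
  set.seed(101)
  n <- 100
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(signal = as.numeric(y) + stats::rnorm(n, 0, 0.05),
             noise = stats::runif(n))
  sc <- relieff_scores(X, y, k_neighbors = 10)
  expect_gt(sc$scores[1], sc$scores[2])
  expect_true(all(abs(sc$scores) <= 1 + 1e-9))
  s1 <- relieff_scores(X, y, m_samples = 30, seed = 5)
  s2 <- relieff_scores(X, y, m_samples = 30, seed = 5)
  expect_identical(s1$scores, s2$scores)
  expect_error(relieff_scores(X[41:60, ], y[41:60], k_neighbors = 10),
               "fewer than")
})

test_that("CFS merit collapses, caps and stays affine-invariant", {
  set.seed(31)
  n <- 60
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(a = as.numeric(y) + stats::rnorm(n, 0, 0.5),
             b = stats::rnorm(n), c = stats::runif(n))
  # singleton: merit = |r_cf|
  expect_equal(cfs_merit(X, y, 1),
               abs(stats::cor(X[, 1], as.numeric(y))))
  # duplicated dimension: r_ff = 1 -> merit = |r_cf| again
  expect_equal(cfs_merit(cbind(X[, 1], X[, 1]), y, c(1, 2)),
               abs(stats::cor(X[, 1], as.numeric(y))), tolerance = 1e-12)
  # formula check against independently aggregated correlations
  rcf <- mean(abs(stats::cor(X[, 1:2], as.numeric(y))))
  rff <- abs(stats::cor(X[, 1], X[, 2]))
  expect_equal(cfs_merit(X, y, 1:2), 2 * rcf / sqrt(2 + 2 * rff))
  # affine transforms of member dimensions change nothing
  X2 <- cbind(3 * X[, 1] - 7, -0.5 * X[, 2] + 2, X[, 3])
  expect_equal(cfs_merit(X2, y, 1:3), cfs_merit(X, y, 1:3))
  # zero-variance member treated as correlation 0, with a message
  expect_message(m0 <- cfs_merit(cbind(X[, 1], 1), y, 1:2), "zero-variance")
  expect_error(cfs_merit(X, y, integer(0)), "empty")
})

test_that("CFS genetic selection matches exhaustive search on 10 dims", {
  set.seed(91)
  n <- 40
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- matrix(stats::runif(n * 10), n)
  X[, 3] <- as.numeric(y) + stats::rnorm(n, 0, 0.4)
  X[, 8] <- as.numeric(!y) + stats::rnorm(n, 0, 0.4)
  oracle <- exhaustive_best(function(d) cfs_merit(X, y, d), 10)
  got <- cfs_select(X, y, ga_params(pop_size = 40, generations = 60,
                                    seed = 17))
  expect_equal(got$fitness, oracle$fitness, tolerance = 1e-12)
  expect_identical(sort(got$dims), oracle$dims)
  expect_true(all(c(3, 8) %in% got$dims))   # planted dims recovered
  # fixed seed -> identical subset across runs
  again <- cfs_select(X, y, ga_params(pop_size = 40, generations = 60,
                                      seed = 17))
  expect_identical(got$dims, again$dims)
})

test_that("top_k returns nested, deterministically tie-broken subsets", {
  sc <- promstruct:::dimension_scores("IG", c(5, 3, 3, 9, 1, 3, 0, 9))
  subs <- top_k(sc, c(2, 4, 8))
  expect_identical(names(subs), c("2", "4", "8"))
  expect_identical(subs[["2"]]$dims, c(4L, 8L))       # ties: lower dim first
  expect_identical(subs[["4"]]$dims, c(4L, 8L, 1L, 2L))
  expect_identical(sort(subs[["8"]]$dims), 1:8)       # size = D -> all dims
  expect_true(all(subs[["2"]]$dims %in% subs[["4"]]$dims))
  expect_true(all(subs[["4"]]$dims %in% subs[["8"]]$dims))
  expect_error(top_k(sc, 9), "sizes")
})
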