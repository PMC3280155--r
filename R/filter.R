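entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Fayyad-Irani MDL stopping rule for one candidate split of labels `y`
# (sorted by x) at position `cut_at` (left part = 1..cut_at).
mdl_gain_ok <- function(y_left, y_right) {
  n <- length(y_left) + length(y_right)
  ent <- function(v) entropy_bits(table(v))
  k <- length(unique(c(y_left, y_right)))
  k1 <- length(unique(y_left)); k2 <- length(unique(y_right))
  e <- ent(c(y_left, y_right)); e1 <- ent(y_left); e2 <- ent(y_right)
  gain <- e - (length(y_left) * e1 + length(y_right) * e2) / n
  delta <- log2(3^k - 2) - (k * e - k1 * e1 - k2 * e2)
  gain > (log2(n - 1) + delta) / n
}

# Candidate boundary cuts for sorted (x, y); returns, for the best cut,
# the index (size of the left part) and the cut value, or NULL.
best_cut <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NULL)
  # candidate cuts only between distinct adjacent x values
  cand <- which(diff(x) > 0)
  if (!length(cand)) return(NULL)
  yl <- cumsum(y); yr <- sum(y) - yl
  nl <- seq_len(n); nr <- n - nl
  h <- function(a, b) {  # entropy of a two-class count pair, vectorized
    t <- a + b
    out <- numeric(length(t))
    nz <- t > 0
    pa <- a[nz] / t[nz]; pb <- b[nz] / t[nz]
    term <- function(p) ifelse(p > 0, -p * log2(p), 0)
    out[nz] <- term(pa) + term(pb)
    out
  }
  went <- (nl[cand] * h(yl[cand], nl[cand] - yl[cand]) +
             nr[cand] * h(yr[cand], nr[cand] - yr[cand])) / n
  i <- cand[which.min(went)]
  list(at = i, value = (x[i] + x[i + 1]) / 2)
}

mdl_cuts_rec <- function(x, y) {
  bc <- best_cut(x, y)
  if (is.null(bc)) return(numeric(0))
  left <- seq_len(bc$at)
  if (!mdl_gain_ok(y[left], y[-left])) return(numeric(0))
  c(mdl_cuts_rec(x[left], y[left]), bc$value,
    mdl_cuts_rec(x[-left], y[-left]))
}

#' Supervised MDL discretization
#'
#' Fayyad-Irani recursive minimal-description-length binning per dimension,
#' the preprocessing step feeding the information-gain and chi-square
#' criteria (both need discrete inputs; the structural profiles are
#' continuous). Dimensions where no cut passes the MDL test collapse to a
#' single bin and therefore score 0 under both criteria.
#'
#' @param X numeric matrix (samples x dims).
#' @param y logical labels.
#' @return List with `Xd` (integer bin matrix, bins numbered from 1) and
#'   `cuts` (list of per-dimension cut values).
#' @export
discretize_mdl <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples")
  y <- as.logical(y)
  cuts <- vector("list", ncol(X))
  Xd <- matrix(1L, nrow(X), ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    cj <- mdl_cuts_rec(X[o, j], y[o])
    cuts[[j]] <- cj
    if (length(cj)) Xd[, j] <- findInterval(X[, j], cj) + 1L
  }
  list(Xd = Xd, cuts = cuts)
}

dimension_scores <- function(method, scores, params = list()) {
  structure(list(method = method, scores = scores, params = params),
            class = "dimension_scores")
}

#' @export
print.dimension_scores <- function(x, ...) {
  cat(sprintf("<dimension_scores> %s over %d dims; top score %.4g\n",
              x$method, length(x$scores), max(x$scores)))
  invisible(x)
}

#' Information-gain scores
#'
#' `score_d = H(y) - H(y | X_d)` in bits, on MDL-discretized dimensions.
#'
#' @param Xd integer bin matrix from [discretize_mdl()] (or any discrete
#'   matrix).
#' @param y logical labels.
#' @return A `dimension_scores` (method `"IG"`).
#' @export
ig_scores <- function(Xd, y) {
  y <- as.logical(y)
  hy <- entropy_bits(table(y))
  n <- length(y)
  sc <- apply(as.matrix(Xd), 2, function(col) {
    tab <- table(col, y)
    hy - sum(rowSums(tab) / n * apply(tab, 1, entropy_bits))
  })
  dimension_scores("IG", pmax(sc, 0))
}

#' Chi-square scores
#'
#' Pearson chi-square statistic of each dimension-by-label contingency
#' table (no continuity correction); single-bin dimensions score 0.
#'
#' @inheritParams ig_scores
#' @return A `dimension_scores` (method `"CHI"`).
#' @export
chi2_scores <- function(Xd, y) {
  y <- as.logical(y)
  sc <- apply(as.matrix(Xd), 2, function(col) {
    tab <- table(col, y)
    if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  })
  dimension_scores("CHI", sc)
}

#' ReliefF scores
#'
#' Standard ReliefF weighting: for each sampled instance, dimension weights
#' decrease by the mean per-dimension difference to the `k_neighbors`
#' nearest hits and increase by the class-prior-weighted mean difference to
#' the nearest misses of each other class. Differences are Manhattan per
#' dimension, normalized by the dimension's observed range; weights are
#' averaged over the sampled instances, so for `[0,1]`-scaled inputs they
#' lie in `[-1, 1]`.
#'
#' @param X numeric matrix (samples x dims), `[0,1]`-scaled.
#' @param y logical labels; every class needs `> k_neighbors` members.
#' @param k_neighbors hits/misses per instance.
#' @param m_samples instances to sample (`NULL` = all, the default).
#' @param seed RNG seed used only when `m_samples < n`.
#' @return A `dimension_scores` (method `"ReliefF"`).
#' @export
relieff_scores <- function(X, y, k_neighbors = 10, m_samples = NULL,
                           seed = NULL) {
  X <- as.matrix(X)
  y <- as.logical(y)
  n <- nrow(X)
  classes <- unique(y)
  for (cl in classes)
    if (sum(y == cl) < k_neighbors + 1)
      stop("class ", cl, " has fewer than k_neighbors + 1 = ",
           k_neighbors + 1, " members")
  rng <- apply(X, 2, function(col) diff(range(col)))
  denom <- ifelse(rng == 0, Inf, rng)
  Xn <- sweep(X, 2, denom, "/")          # constant dims contribute diff 0
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  prior <- vapply(classes, function(cl) mean(y == cl), 0)
  names(prior) <- as.character(classes)
  samp <- if (is.null(m_samples) || m_samples >= n) seq_len(n)
  else with_seed(seed, sample.int(n, m_samples))
  W <- numeric(ncol(X))
  for (i in samp) {
    for (cl in classes) {
      members <- setdiff(which(y == cl), i)
      k <- min(k_neighbors, length(members))
      nn <- members[order(D[i, members])[seq_len(k)]]
      diffs <- colMeans(abs(sweep(Xn[nn, , drop = FALSE], 2, Xn[i, ])))
      if (cl == y[i]) {
        W <- W - diffs
      } else {
        w <- prior[as.character(cl)] / (1 - prior[as.character(y[i])])
        W <- W + w * diffs
      }
    }
  }
  dimension_scores("ReliefF", W / length(samp),
                   params = list(k_neighbors = k_neighbors,
                                 m_samples = length(samp), seed = seed))
}

#' CFS merit of a dimension subset
#'
#' `merit = s * rcf / sqrt(s + s (s - 1) rff)` where `s` is the subset
#' size, `rcf` the mean absolute Pearson correlation between member
#' dimensions and the label, and `rff` the mean absolute pairwise
#' correlation within the subset — rewarding class-correlated, mutually
#' uncorrelated dimensions. Correlations undefined on zero-variance
#' dimensions are treated as 0 (with a message).
#'
#' @param X numeric matrix.
#' @param y logical labels.
#' @param subset dimension indices, non-empty.
#' @return Scalar merit.
#' @export
cfs_merit <- function(X, y, subset) {
  if (length(subset) == 0) stop("empty subset")
  Xs <- as.matrix(X)[, subset, drop = FALSE]
  yv <- as.numeric(as.logical(y))
  s <- length(subset)
  sds <- apply(Xs, 2, stats::sd)
  if (any(sds == 0))
    message("cfs_merit: ", sum(sds == 0),
            " zero-variance dimension(s); correlation treated as 0")
  rcf <- suppressWarnings(abs(stats::cor(Xs, yv)))
  rcf[is.na(rcf)] <- 0
  rcf_bar <- mean(rcf)
  if (s == 1) return(unname(rcf_bar))
  C <- suppressWarnings(abs(stats::cor(Xs)))
  C[is.na(C)] <- 0
  rff_bar <- mean(C[upper.tri(C)])
  unname(s * rcf_bar / sqrt(s + s * (s - 1) * rff_bar))
}

#' CFS subset selection by genetic search
#'
#' Searches dimension subsets maximizing [cfs_merit()] with the bitstring
#' genetic algorithm of [genetic_search()]. The subset size is emergent,
#' not requested.
#'
#' @param X numeric matrix.
#' @param y logical labels.
#' @param params a [ga_params()].
#' @return A `selected_subset` (method `"CFS"`).
#' @export
cfs_select <- function(X, y, params = ga_params()) {
  X <- as.matrix(X)
  res <- genetic_search(function(dims) cfs_merit(X, y, dims),
                        n_dims = ncol(X), params = params)
  res$method <- "CFS"
  res
}

selected_subset <- function(dims, method, params = list(), scores = NULL,
                            fitness = NULL, trace = NULL, seed = NULL) {
  structure(list(dims = as.integer(dims), size = length(dims),
                 method = method, params = params, scores = scores,
                 fitness = fitness, trace = trace, seed = seed),
            class = "selected_subset")
}

#' @export
print.selected_subset <- function(x, ...) {
  cat(sprintf("<selected_subset> %s: %d dims%s\n", x$method, x$size,
              if (!is.null(x$fitness)) sprintf(", fitness %.4g", x$fitness)
              else ""))
  invisible(x)
}

#' Top-k dimension subsets from filter scores
#'
#' For each requested size, the highest-scoring dimensions; ties broken by
#' lower dimension index, so subsets are deterministic and nested.
#'
#' @param scores a `dimension_scores`.
#' @param sizes subset sizes, e.g. `c(100, 200, 300, 400, 500)`.
#' @return Named list of `selected_subset`s (one per size).
#' @export
top_k <- function(scores, sizes = c(100, 200, 300, 400, 500)) {
  stopifnot(inherits(scores, "dimension_scores"))
  D <- length(scores$scores)
  if (any(sizes < 1 | sizes > D))
    stop("sizes must lie in 1..", D)
  o <- order(-scores$scores, seq_len(D))
  out <- lapply(sizes, function(s)
    selected_subset(o[seq_len(s)], method = scores$method,
                    params = c(scores$params, list(size = s)),
                    scores = scores$scores[o[seq_len(s)]]))
  stats::setNames(out, as.character(sizes))
}

#' Write a selected subset as TSV
#'
#' Columns: rank, dim, feature, position, score (when available).
#'
#' @param subset a `selected_subset`.
#' @param fm the `feature_matrix` supplying the dimension index.
#' @param file output path.
#' @export
write_subset <- function(subset, fm, file) {
  ix <- fm$index[subset$dims, ]
  df <- data.frame(rank = seq_along(subset$dims), dim = subset$dims,
                   feature = ix$feature, position = ix$position)
  if (!is.null(subset$scores)) df$score <- subset$scores
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
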