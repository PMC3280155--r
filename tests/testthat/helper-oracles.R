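# Independent oracles used to freeze or cross-check expected values.
# These deliberately re-derive results from first principles and share no
# code with the implementation paths they check.

# Toy dinucleotide scale: values 1..16 over lexicographic dinucleotides.
toy_scale_16 <- function() {
  km <- sort(as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0)))
  property_scale("toy16", stats::setNames(1:16, km))
}

uniform_scale <- function(k = 2, value = 3) {
  b <- c("A", "C", "G", "T")
  km <- sort(apply(expand.grid(rep(list(b), k))[, k:1, drop = FALSE],
                   1, paste, collapse = ""))
  property_scale(paste0("const", k), stats::setNames(rep(value, 4^k), km))
}

# brute-force ReliefF: literal transcription of the update rule, O(n^2 D)
relieff_oracle <- function(X, y, k_neighbors) {
  X <- as.matrix(X); y <- as.logical(y); n <- nrow(X)
  rng <- apply(X, 2, function(c) diff(range(c)))
  dn <- ifelse(rng == 0, Inf, rng)
  Xn <- sweep(X, 2, dn, "/")
  W <- numeric(ncol(X))
  for (i in seq_len(n)) {
    d <- sapply(seq_len(n), function(j) sum(abs(Xn[i, ] - Xn[j, ])))
    for (cl in unique(y)) {
      memb <- setdiff(which(y == cl), i)
      nn <- memb[order(d[memb])[seq_len(min(k_neighbors, length(memb)))]]
      md <- colMeans(abs(sweep(Xn[nn, , drop = FALSE], 2, Xn[i, ])))
      if (cl == y[i]) W <- W - md
      else W <- W + (mean(y == cl) / (1 - mean(y == y[i]))) * md
    }
  }
  W / n
}

# exhaustive best subset for any deterministic fitness over n_dims <= 20
exhaustive_best <- function(fitness, n_dims) {
  best <- NULL; best_fit <- -Inf
  for (code in seq_len(2^n_dims - 1)) {
    dims <- which(bitwAnd(code, 2^(seq_len(n_dims) - 1)) > 0)
    f <- fitness(dims)
    if (f > best_fit) { best_fit <- f; best <- dims }
  }
  list(dims = best, fitness = best_fit)
}

# AUC by direct concordant-pair counting (ties count 1/2)
auc_oracle <- function(scores, y) {
  pos <- scores[y]; neg <- scores[!y]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# brute-force evaluation of the single best entropy cut plus the MDL
# acceptance rule, scanning every midpoint between adjacent sorted values
mdl_cut_oracle <- function(x, y) {
  o <- order(x); x <- x[o]; y <- y[o]; n <- length(x)
  H <- function(v) {
    if (!length(v)) return(0)
    p <- table(v) / length(v); p <- p[p > 0]
    -sum(p * log2(p))
  }
  best <- NULL; best_e <- Inf
  for (i in seq_len(n - 1)) {
    if (x[i] == x[i + 1]) next
    e <- (i * H(y[1:i]) + (n - i) * H(y[(i + 1):n])) / n
    if (e < best_e) { best_e <- e; best <- i }
  }
  if (is.null(best)) return(numeric(0))
  l <- y[1:best]; r <- y[(best + 1):n]
  gain <- H(y) - best_e
  k <- length(unique(y)); k1 <- length(unique(l)); k2 <- length(unique(r))
  delta <- log2(3^k - 2) - (k * H(y) - k1 * H(l) - k2 * H(r))
  if (gain > (log2(n - 1) + delta) / n) (x[best] + x[best + 1]) / 2
  else numeric(0)
}

# quick labeled set without the simulator (deterministic sequences)
tiny_set <- function(n = 6, L = 251) {
  base <- paste(rep(c("A", "C", "G", "T"), length.out = L), collapse = "")
  alt <- paste(rep(c("G", "T", "A", "C"), length.out = L), collapse = "")
  labeled_sequence_set(
    stats::setNames(rep(c(base, alt), length.out = n), paste0("s", 1:n)),
    rep(c(TRUE, FALSE), length.out = n))
}
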