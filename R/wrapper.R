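#' Genetic-algorithm parameters
#'
#' Defaults follow the common data-mining-toolkit settings: population 20,
#' 20 generations, crossover probability 0.6, per-bit mutation 0.033,
#' elitism 1.
#'
#' @param pop_size population size (>= 2).
#' @param generations number of generations.
#' @param p_crossover single-point crossover probability.
#' @param p_mutation per-bit mutation probability.
#' @param elitism individuals copied unchanged into the next generation.
#' @param seed RNG seed; fixed seed makes the whole search deterministic.
#' @return A `ga_params` list.
#' @export
ga_params <- function(pop_size = 20, generations = 20, p_crossover = 0.6,
                      p_mutation = 0.033, elitism = 1, seed = NULL) {
  stopifnot(pop_size >= 2, generations >= 1,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1,
            elitism >= 0, elitism < pop_size)
  structure(list(pop_size = pop_size, generations = generations,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism = elitism, seed = seed),
            class = "ga_params")
}

#' Bitstring genetic search over dimension subsets
#'
#' One bit per dimension; tournament selection (size 2), single-point
#' crossover, per-bit mutation and elitism. Empty subsets get fitness
#' `-Inf`. Returns the best-ever subset plus the per-generation best-ever
#' fitness trace (non-decreasing by elitism).
#'
#' @param fitness function(integer dims) -> scalar; called on the indices
#'   of the set bits.
#' @param n_dims number of dimensions.
#' @param params a [ga_params()].
#' @return A `selected_subset` with `fitness` and `trace`.
#' @export
genetic_search <- function(fitness, n_dims, params = ga_params()) {
  stopifnot(n_dims >= 1)
  with_seed(params$seed, genetic_search_impl(fitness, n_dims, params))
}

genetic_search_impl <- function(fitness, n_dims, params) {
  np <- params$pop_size
  pop <- matrix(stats::runif(np * n_dims) < 0.5, np, n_dims)
  evaluate <- function(bits) {
    dims <- which(bits)
    if (!length(dims)) return(-Inf)
    val <- fitness(dims)
    if (!is.finite(val) && !identical(val, -Inf))
      stop("fitness evaluator returned ", val, " for subset of size ",
           length(dims))
    val
  }
  fit <- apply(pop, 1, evaluate)
  best_bits <- pop[which.max(fit), ]
  best_fit <- max(fit)
  trace <- numeric(params$generations)
  for (g in seq_len(params$generations)) {
    new_pop <- matrix(FALSE, np, n_dims)
    n_elite <- params$elitism
    if (n_elite > 0)
      new_pop[seq_len(n_elite), ] <- pop[order(-fit)[seq_len(n_elite)], ,
                                         drop = FALSE]
    i <- n_elite
    while (i < np) {
      pick <- function() {   # tournament of 2
        c2 <- sample.int(np, 2)
        pop[c2[which.max(fit[c2])], ]
      }
      p1 <- pick(); p2 <- pick()
      if (stats::runif(1) < params$p_crossover && n_dims > 1) {
        cut <- sample.int(n_dims - 1, 1)
        c1 <- c(p1[seq_len(cut)], p2[-seq_len(cut)])
        cc2 <- c(p2[seq_len(cut)], p1[-seq_len(cut)])
      } else {
        c1 <- p1; cc2 <- p2
      }
      for (child in list(c1, cc2)) {
        if (i >= np) break
        flip <- stats::runif(n_dims) < params$p_mutation
        child <- xor(child, flip)
        i <- i + 1
        new_pop[i, ] <- child
      }
    }
    pop <- new_pop
    fit <- apply(pop, 1, evaluate)
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best_bits <- pop[which.max(fit), ]
    }
    trace[g] <- best_fit
  }
  selected_subset(which(best_bits), method = "GA", params = params,
                  fitness = best_fit, trace = trace, seed = params$seed)
}

# mean stratified cross-validated accuracy on a dimension subset
cv_accuracy <- function(X, y, dims, classifier, folds, seed) {
  fold_id <- stratified_folds(y, folds, seed)
  correct <- 0
  for (f in seq_len(folds)) {
    test <- fold_id == f
    cl <- train_classifier(X[!test, dims, drop = FALSE], y[!test],
                           classifier = classifier)
    sc <- predict(cl, X[test, dims, drop = FALSE])
    correct <- correct + sum((sc > cl$threshold) == y[test])
  }
  correct / length(y)
}

#' Wrapper feature selection
#'
#' Genetic search whose fitness is the mean `cv_folds`-fold
#' cross-validated accuracy of the target classifier restricted to the
#' candidate dimensions — accuracy, not F-measure, scores candidates; a
#' final [cross_validate()] on the chosen subset reports full metrics.
#'
#' @param fm a `feature_matrix`.
#' @param classifier `"svm"` or `"knn"`.
#' @param params a [ga_params()].
#' @param cv_folds folds for the fitness estimate.
#' @return A `selected_subset` (method `"wrapper-svm"` / `"wrapper-knn"`)
#'   with the final `metrics_report` in `$evaluation`.
#' @export
wrapper_select <- function(fm, classifier = c("svm", "knn"),
                           params = ga_params(), cv_folds = 5) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(fm, "feature_matrix"), cv_folds >= 2)
  if (length(unique(fm$y)) < 2) stop("both classes required")
  fold_seed <- if (is.null(params$seed)) 1L else params$seed
  res <- genetic_search(
    function(dims) cv_accuracy(fm$X, fm$y, dims, classifier, cv_folds,
                               seed = fold_seed),
    n_dims = ncol(fm$X), params = params)
  res$method <- paste0("wrapper-", classifier)
  res$params <- c(res$params, list(classifier = classifier,
                                   cv_folds = cv_folds))
  # outer evaluation on a different fold split than the GA optimized
  res$evaluation <- cross_validate(fm, subset = res,
                                   classifier = classifier,
                                   folds = cv_folds, seed = fold_seed + 1L)
  res
}
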