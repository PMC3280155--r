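#' Build the concatenated, normalized feature matrix
#'
#' Each sequence is converted under every scale ([convert_sequence()]
#' semantics), each feature block is min-max normalized to `[0, 1]` using
#' that scale's theoretical extrema (`vmin`, `vmax` — not the observed
#' data, so construction is deterministic and train/test identical), and
#' the blocks are concatenated in the given scale order. With the 13
#' default scales and the 251-nt window the dimension is 13 x 251 = 3263.
#'
#' @param set a [labeled_sequence_set()].
#' @param scales ordered list of [property_scale()]s; the order fixes the
#'   dimension numbering.
#' @param positions TSS-relative window coordinates.
#' @return A `feature_matrix`: list with `X` (samples x D, entries in
#'   `[0,1]`), `y` (logical labels), `index` (`data.frame` `dim`,
#'   `feature`, `position`), `normalization` (per-feature bounds).
#' @export
build_matrix <- function(set, scales = default_scales(),
                         positions = window_positions()) {
  stopifnot(inherits(set, "labeled_sequence_set"))
  if (length(set$sequences) < 2 || length(unique(set$labels)) < 1)
    stop("need at least 2 samples")
  if (length(scales) == 0) stop("need at least one scale")
  blocks <- vector("list", length(scales))
  idx <- vector("list", length(scales))
  for (i in seq_along(scales)) {
    sc <- scales[[i]]
    if (sc$vmin >= sc$vmax)
      stop("degenerate scale '", sc$name, "': vmin == vmax")
    m <- convert_many(set$sequences, sc, positions = positions)
    # clamp: smoothing arithmetic can undershoot vmin by float epsilon
    blocks[[i]] <- pmin(pmax((m - sc$vmin) / (sc$vmax - sc$vmin), 0), 1)
    idx[[i]] <- data.frame(feature = sc$name, position = positions)
  }
  X <- do.call(cbind, blocks)
  index <- do.call(rbind, idx)
  index <- data.frame(dim = seq_len(nrow(index)), index)
  colnames(X) <- paste0(index$feature, "@", index$position)
  norm <- data.frame(feature = vapply(scales, `[[`, "", "name"),
                     vmin = vapply(scales, `[[`, 0, "vmin"),
                     vmax = vapply(scales, `[[`, 0, "vmax"))
  structure(list(X = X, y = set$labels, index = index,
                 normalization = list(method = "minmax-scale-bounds",
                                      bounds = norm)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d dims (%d features x %d positions), %d promoter / %d non-promoter\n",
              nrow(x$X), ncol(x$X), length(unique(x$index$feature)),
              length(unique(x$index$position)), sum(x$y), sum(!x$y)))
  invisible(x)
}

#' Dimensions belonging to one feature
#'
#' @param fm a [build_matrix()] result.
#' @param feature feature name.
#' @return Integer vector of dimension indices (1-based, contiguous, in
#'   position order).
#' @export
dims_for_feature <- function(fm, feature) {
  stopifnot(inherits(fm, "feature_matrix"))
  d <- fm$index$dim[fm$index$feature == feature]
  if (length(d) == 0) stop("unknown feature: ", feature)
  d
}

#' Export a feature matrix as TSV
#'
#' Column headers encode `feature@position`; the label column `promoter`
#' is appended last.
#'
#' @param fm a `feature_matrix`.
#' @param file output path.
#' @export
write_matrix <- function(fm, file) {
  df <- data.frame(id = rownames(fm$X), fm$X, promoter = fm$y,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
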