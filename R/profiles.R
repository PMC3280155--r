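BASES <- c("A", "C", "G", "T")

#' TSS-relative window coordinates
#'
#' Position 0 is the transcription start site base; the default window spans
#' 200 bp upstream to 50 bp downstream inclusive, i.e. 251 positions.
#'
#' @param up,down bases upstream / downstream of the TSS.
#' @return Integer vector `-up:down`.
#' @export
window_positions <- function(up = 200, down = 50) seq.int(-up, down)

encode_bases <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], BASES)
}

#' Raw structural profile of one sequence
#'
#' Replaces each k-mer of `seq` by its value under `scale`, left-aligned to
#' the k-mer's first base. K-mers containing a non-ACGT character take the
#' mean of the scale's values; sequences with more than `max_ambiguous`
#' ambiguous bases are rejected as junk.
#'
#' @param seq DNA string, length >= `scale$k`.
#' @param scale a [property_scale()].
#' @param max_ambiguous maximum tolerated fraction of non-ACGT bases.
#' @return Numeric vector of length `nchar(seq) - scale$k + 1`.
#' @examples
#' sc <- default_scales("duplex_free_energy")[[1]]
#' raw_profile("AACA", sc)
#' @export
raw_profile <- function(seq, scale, max_ambiguous = 0.1) {
  stopifnot(inherits(scale, "property_scale"))
  L <- nchar(seq)
  k <- scale$k
  if (L < k)
    stop("sequence of length ", L, " is shorter than k = ", k)
  codes <- encode_bases(seq)
  n_amb <- sum(is.na(codes))
  if (n_amb > max_ambiguous * L)
    stop("sequence has ", n_amb, "/", L, " ambiguous bases (> ",
         max_ambiguous * 100, "% allowed)")
  idx <- kmer_index(matrix(codes, nrow = 1), k)
  vals <- scale$values[idx]
  vals[is.na(idx)] <- mean(scale$values)
  as.vector(vals)
}

# codes: integer matrix (n x L) in 1..4 with NA for ambiguous bases.
# Returns n x (L-k+1) matrix of 1-based k-mer indices into the
# lexicographically ordered value table; NA where any base is ambiguous.
kmer_index <- function(codes, k) {
  L <- ncol(codes)
  w <- L - k + 1
  idx <- codes[, seq_len(w), drop = FALSE] - 1L
  for (j in seq_len(k - 1L))
    idx <- idx * 4L + (codes[, j + seq_len(w), drop = FALSE] - 1L)
  idx + 1L
}

#' Sliding-window smoothing
#'
#' Centered moving average with window size 3 nt and step 1 bp by default.
#' With `pad = TRUE` the ends are replicated `(window-1)/2` times first so
#' the output keeps the input length; with `pad = FALSE` only full windows
#' are returned (length `length(raw) - window + 1`).
#'
#' @param raw numeric vector.
#' @param window odd positive window size.
#' @param step positive step size; windows are taken every `step` positions.
#' @param pad replicate terminal values before smoothing.
#' @return Numeric vector of smoothed values.
#' @examples
#' smooth_profile(c(1, 2, 3, 4))            # 4/3 2 3 11/3
#' smooth_profile(c(1, 2, 3, 4), pad = FALSE)  # 2 3
#' @export
smooth_profile <- function(raw, window = 3, step = 1, pad = TRUE) {
  if (length(raw) == 0) stop("empty profile")
  stopifnot(window >= 1, window %% 2 == 1, step >= 1)
  h <- (window - 1) / 2
  x <- if (pad) c(rep(raw[1], h), raw, rep(raw[length(raw)], h)) else raw
  if (window > length(x))
    stop("window (", window, ") larger than padded profile (", length(x), ")")
  cs <- cumsum(c(0, x))
  n_out <- length(x) - window + 1
  sm <- (cs[window + seq_len(n_out)] - cs[seq_len(n_out)]) / window
  sm[seq.int(1, n_out, by = step)]
}

#' Convert a promoter window into a structural profile
#'
#' Applies `scale` along the window, right-pads the raw profile by
#' replicating its terminal value `k - 1` times so every feature keeps the
#' full window dimensionality (251 for the default -200..+50 window), then
#' smooths with [smooth_profile()].
#'
#' @param seq DNA string whose length equals `length(positions)`.
#' @param scale a [property_scale()].
#' @param positions TSS-relative coordinates of the window.
#' @param window,step smoothing parameters, see [smooth_profile()].
#' @return A `structural_profile`: list with `feature`, `values`,
#'   `positions` (values parallel to positions).
#' @export
convert_sequence <- function(seq, scale, positions = window_positions(),
                             window = 3, step = 1) {
  if (nchar(seq) != length(positions))
    stop("sequence length ", nchar(seq), " does not match window length ",
         length(positions))
  raw <- raw_profile(seq, scale)
  raw <- c(raw, rep(raw[length(raw)], scale$k - 1L))
  structure(
    list(feature = scale$name,
         values = smooth_profile(raw, window = window, step = step),
         positions = positions),
    class = "structural_profile")
}

#' @export
print.structural_profile <- function(x, ...) {
  cat(sprintf("<structural_profile> %s: %d positions [%d..%d]\n",
              x$feature, length(x$values), min(x$positions), max(x$positions)))
  invisible(x)
}

# Vectorized converter: n sequences -> n x window matrix, identical
# per-row semantics to convert_sequence(). Backbone of build_matrix().
convert_many <- function(seqs, scale, positions = window_positions(),
                         window = 3, max_ambiguous = 0.1) {
  L <- length(positions)
  n <- length(seqs)
  if (any(nchar(seqs) != L))
    stop("all sequences must have the window length ", L)
  codes <- matrix(match(unlist(strsplit(toupper(seqs), ""), use.names = FALSE),
                        BASES), nrow = n, byrow = TRUE)
  n_amb <- rowSums(is.na(codes))
  if (any(bad <- n_amb > max_ambiguous * L))
    stop(sum(bad), " sequence(s) exceed ", max_ambiguous * 100,
         "% ambiguous bases (first: ",
         if (is.null(names(seqs))) which(bad)[1] else names(seqs)[bad][1], ")")
  k <- scale$k
  idx <- kmer_index(codes, k)
  vals <- matrix(scale$values[idx], nrow = n)
  vals[is.na(idx)] <- mean(scale$values)
  if (k > 1)  # right-replicate terminal raw value up to window length
    vals <- cbind(vals, vals[, rep.int(ncol(vals), k - 1L), drop = FALSE])
  h <- (window - 1) / 2
  padded <- cbind(vals[, rep.int(1L, h), drop = FALSE], vals,
                  vals[, rep.int(L, h), drop = FALSE])
  sm <- matrix(0, n, L)
  for (o in seq_len(window)) sm <- sm + padded[, o + 0:(L - 1), drop = FALSE]
  sm <- sm / window
  dimnames(sm) <- list(names(seqs), positions)
  sm
}

#' Position-wise average structural profile
#'
#' Converts each sequence with [convert_sequence()] (smoothing per sequence)
#' and averages position-wise — the profile-plot statistic used to compare
#' promoter against non-promoter structure.
#'
#' @inheritParams convert_many
#' @param seqs character vector of equal-length DNA strings.
#' @return Numeric vector named by TSS-relative position.
#' @export
average_profile <- function(seqs, scale, positions = window_positions(),
                            window = 3) {
  if (length(seqs) < 1) stop("need at least one sequence")
  if (length(unique(nchar(seqs))) != 1)
    stop("sequences differ in length")
  m <- convert_many(seqs, scale, positions = positions, window = window)
  stats::setNames(colMeans(m), positions)
}

#' Export profiles as TSV
#'
#' `write_profiles()` writes a sequence-by-position matrix;
#' `write_average_profiles()` writes one averaged profile per scale
#' (long format: feature, position, value), ready for plotting.
#'
#' @param seqs named character vector of window sequences.
#' @param scale,scales scale / list of scales.
#' @param file output path.
#' @inheritParams convert_many
#' @return The written data, invisibly.
#' @export
write_profiles <- function(seqs, scale, file, positions = window_positions()) {
  m <- convert_many(seqs, scale, positions = positions)
  df <- data.frame(id = if (is.null(names(seqs))) seq_along(seqs)
                   else names(seqs), m, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @rdname write_profiles
#' @export
write_average_profiles <- function(seqs, scales, file,
                                   positions = window_positions()) {
  rows <- lapply(scales, function(sc)
    data.frame(feature = sc$name, position = positions,
               value = unname(average_profile(seqs, sc, positions))))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
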