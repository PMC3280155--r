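#' Structural property scales
#'
#' A `property_scale` maps every di- or trinucleotide over `{A,C,G,T}` to a
#' biophysical value (free energies in kcal/mol, twists in degrees, ...).
#' Thirteen default scales are bundled under
#' `system.file("extdata", "scales", package = "promstruct")`; see
#' [default_scales()]. The conversion machinery is scale-agnostic, so a
#' corrected or additional table can be supplied without code changes.
#'
#' @param name feature identifier.
#' @param values named numeric vector covering all `4^k` k-mers, `k` 2 or 3.
#' @return An object of class `property_scale` with fields `name`, `k`,
#'   `values` (in lexicographic k-mer order), `vmin`, `vmax`.
#' @examples
#' sc <- property_scale("toy", c(AA = 1, AC = 2, AG = 3, AT = 4,
#'                               CA = 5, CC = 6, CG = 7, CT = 8,
#'                               GA = 9, GC = 10, GG = 11, GT = 12,
#'                               TA = 13, TC = 14, TG = 15, TT = 16))
#' sc$k
#' @export
property_scale <- function(name, values) {
  if (is.null(names(values)) || anyNA(suppressWarnings(as.numeric(values))))
    stop("'values' must be a fully named numeric vector")
  values <- stats::setNames(as.numeric(values), toupper(names(values)))
  kl <- unique(nchar(names(values)))
  if (length(kl) != 1L)
    stop("mixed k-mer lengths in scale '", name, "': ",
         paste(kl, collapse = ", "))
  k <- kl
  if (!k %in% c(2L, 3L))
    stop("k-mer order must be 2 or 3, got ", k)
  expected <- all_kmers(k)
  missing <- setdiff(expected, names(values))
  if (length(missing))
    stop("scale '", name, "' is missing ", length(missing), " of ", 4^k,
         " k-mers (e.g. ", paste(utils::head(missing, 3), collapse = ", "), ")")
  extra <- setdiff(names(values), expected)
  if (length(extra))
    stop("scale '", name, "' has non-ACGT k-mers: ",
         paste(utils::head(extra, 3), collapse = ", "))
  values <- values[expected]
  structure(
    list(name = name, k = as.integer(k), values = values,
         vmin = min(values), vmax = max(values)),
    class = "property_scale")
}

#' @export
print.property_scale <- function(x, ...) {
  cat(sprintf("<property_scale> %s: %d %d-mers, range [%g, %g]\n",
              x$name, length(x$values), x$k, x$vmin, x$vmax))
  invisible(x)
}

all_kmers <- function(k) {
  b <- c("A", "C", "G", "T")
  sort(apply(expand.grid(rep(list(b), k))[, k:1, drop = FALSE],
             1, paste, collapse = ""))
}

#' Read a conversion schema file
#'
#' Schema files are two-column TSV with header `kmer<TAB>value` and optional
#' `#` comment lines. All `4^k` k-mers must be present; missing k-mers are
#' an error, never defaulted.
#'
#' @param path schema file.
#' @param name feature name; default: file name stripped of extensions.
#' @return A [property_scale()].
#' @export
load_scale <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such schema file: ", path)
  if (is.null(name))
    name <- sub("\\.synthetic$", "", sub("\\.tsv$", "", basename(path)))
  tab <- utils::read.delim(path, comment.char = "#",
                           colClasses = c("character", "character"))
  if (!identical(names(tab), c("kmer", "value")))
    stop("schema ", path, ": expected header 'kmer<TAB>value', got '",
         paste(names(tab), collapse = "\t"), "'")
  val <- suppressWarnings(as.numeric(tab$value))
  if (anyNA(val)) {
    bad <- which(is.na(val))[1]
    stop("schema ", path, ": non-numeric value '", tab$value[bad],
         "' for k-mer ", tab$kmer[bad])
  }
  property_scale(name, stats::setNames(val, tab$kmer))
}

#' Load the bundled default scales
#'
#' Returns the thirteen bundled structural scales in the fixed order that
#' also fixes the dimension numbering of the concatenated feature space.
#' Six tables are labelled synthetic stand-ins (see the files' headers and
#' the package vignette); the other seven are transcribed published scales.
#'
#' @param features optional character subset of feature names.
#' @return Named list of [property_scale()] objects.
#' @examples
#' scales <- default_scales()
#' names(scales)
#' @export
default_scales <- function(features = NULL) {
  dir <- system.file("extdata", "scales", package = "promstruct")
  idx <- utils::read.delim(file.path(dir, "index.tsv"))
  if (!is.null(features)) {
    unknown <- setdiff(features, idx$feature)
    if (length(unknown))
      stop("unknown feature(s): ", paste(unknown, collapse = ", "))
    idx <- idx[match(features, idx$feature), ]
  }
  scales <- lapply(seq_len(nrow(idx)), function(i)
    load_scale(file.path(dir, idx$file[i]), name = idx$feature[i]))
  stats::setNames(scales, idx$feature)
}
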