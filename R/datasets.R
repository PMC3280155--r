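#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase DNA strings.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read TSS annotations from BED
#'
#' Expects 6-column BED (0-based, half-open). The TSS of a `+` feature is
#' `start`; of a `-` feature, `end - 1` — i.e. the 5' end on the annotated
#' strand. Duplicate (chrom, pos, strand) records are dropped so each
#' unique TSS appears once. Malformed lines are reported with their line
#' number.
#'
#' @param path BED file.
#' @return `data.frame` with columns `chrom`, `pos` (0-based TSS base),
#'   `strand`, `id` — one row per TSS record.
#' @export
read_tss_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t")
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("BED line ", lineno[which(nf < 6)[1]],
         ": expected >= 6 tab-separated fields, got ", min(nf))
  f <- function(i) vapply(fields, `[[`, "", i)
  start <- suppressWarnings(as.integer(f(2)))
  end <- suppressWarnings(as.integer(f(3)))
  strand <- f(6)
  bad <- which(is.na(start) | is.na(end) | end <= start |
                 !strand %in% c("+", "-"))
  if (length(bad))
    stop("BED line ", lineno[bad[1]], ": malformed record '",
         lines[lineno[bad[1]]], "'")
  rec <- data.frame(chrom = f(1),
                    pos = ifelse(strand == "+", start, end - 1L),
                    strand = strand, id = f(4),
                    stringsAsFactors = FALSE)
  dup <- duplicated(rec[c("chrom", "pos", "strand")])
  if (any(dup))
    message("read_tss_bed: dropped ", sum(dup), " duplicate TSS record(s)")
  rec[!dup, , drop = FALSE]
}

#' A TSS record
#'
#' @param chrom sequence name.
#' @param pos 0-based TSS coordinate.
#' @param strand "+" or "-".
#' @param id label.
#' @return One-row `data.frame` in the layout of [read_tss_bed()].
#' @export
tss_record <- function(chrom, pos, strand, id = NA_character_) {
  stopifnot(pos >= 0, strand %in% c("+", "-"))
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand, id = id,
             stringsAsFactors = FALSE)
}

revcomp <- function(seq) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

#' Extract a strand-aware promoter window
#'
#' Takes the window from `up` bases upstream to `down` bases downstream of
#' the TSS *on the annotated strand*: for `-` records the forward-strand
#' slice `[pos - down, pos + up]` is taken and reverse-complemented, so the
#' returned string always reads 5'->3' with the TSS at position `-0`.
#'
#' @param genome_seq DNA string containing the TSS.
#' @param tss one-row TSS record ([tss_record()]).
#' @param up,down window extent; length is `up + down + 1`.
#' @return DNA string of length `up + down + 1`, or `NA` with a warning if
#'   the window leaves the source sequence.
#' @export
extract_window <- function(genome_seq, tss, up = 200, down = 50) {
  pos <- tss$pos[1]
  strand <- tss$strand[1]
  L <- nchar(genome_seq)
  lo <- if (strand == "+") pos - up else pos - down
  hi <- if (strand == "+") pos + down else pos + up
  if (lo < 0 || hi >= L) {
    warning("window [", lo, ", ", hi, "] for TSS '", tss$id[1],
            "' out of bounds (contig length ", L, "); skipped")
    return(NA_character_)
  }
  w <- substr(genome_seq, lo + 1L, hi + 1L)
  if (strand == "-") w <- unname(revcomp(w)) else w
}

#' Extract windows for a table of TSS records
#'
#' @param genome named character vector (contig name -> sequence).
#' @param tss TSS table as returned by [read_tss_bed()].
#' @inheritParams extract_window
#' @return Named character vector of windows; out-of-bounds records are
#'   skipped with a warning.
#' @export
extract_windows <- function(genome, tss, up = 200, down = 50) {
  out <- character(0)
  for (i in seq_len(nrow(tss))) {
    chrom <- tss$chrom[i]
    if (!chrom %in% names(genome)) {
      warning("TSS '", tss$id[i], "': unknown contig ", chrom, "; skipped")
      next
    }
    w <- extract_window(genome[[chrom]], tss[i, , drop = FALSE], up, down)
    if (!is.na(w)) out[[if (is.na(tss$id[i])) as.character(i)
                        else tss$id[i]]] <- w
  }
  out
}

#' Labeled promoter/non-promoter sequence set
#'
#' @param sequences named character vector of equal-length windows.
#' @param labels logical vector parallel to `sequences`; `TRUE` =
#'   promoter, `FALSE` = non-promoter.
#' @return A `labeled_sequence_set`.
#' @export
labeled_sequence_set <- function(sequences, labels) {
  if (length(sequences) != length(labels))
    stop("sequences and labels differ in length")
  if (anyNA(labels)) stop("labels must be TRUE/FALSE, no NA")
  if (length(unique(nchar(sequences))) > 1)
    stop("sequences differ in length")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  structure(list(sequences = sequences, labels = as.logical(labels)),
            class = "labeled_sequence_set")
}

#' @export
print.labeled_sequence_set <- function(x, ...) {
  cat(sprintf("<labeled_sequence_set> %d sequences of %d nt (%d promoter, %d non-promoter)\n",
              length(x$sequences), nchar(x$sequences[1]),
              sum(x$labels), sum(!x$labels)))
  invisible(x)
}

#' Write / read a labeled sequence set
#'
#' The set is stored as a FASTA file plus a sidecar labels TSV
#' (`<path>.labels.tsv` with columns `id`, `promoter`); reading back is the
#' exact inverse.
#'
#' @param set a [labeled_sequence_set()].
#' @param path FASTA path.
#' @return `read_labeled_set()` returns the set; `write_labeled_set()` the
#'   path, invisibly.
#' @export
write_labeled_set <- function(set, path) {
  write_fasta(set$sequences, path)
  utils::write.table(
    data.frame(id = names(set$sequences), promoter = set$labels),
    paste0(path, ".labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labeled_set
#' @export
read_labeled_set <- function(path) {
  seqs <- read_fasta(path)
  lab <- utils::read.delim(paste0(path, ".labels.tsv"))
  labeled_sequence_set(seqs[lab$id], as.logical(lab$promoter))
}
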