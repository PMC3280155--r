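#' Fit a first-order Markov model of sequence composition
#'
#' Estimates initial-base and transition probabilities from dinucleotide
#' counts, the model used to shuffle promoters into the randomized
#' non-promoter background. A Laplace pseudocount (default 1) keeps every
#' transition reachable so generated negatives have full support; pass
#' `pseudocount = 0` for the bare maximum-likelihood counts.
#'
#' @param seqs character vector of DNA strings, each of length >= 2.
#' @param pseudocount added to every dinucleotide and initial-base count.
#' @return A `markov1_model`: list with `initial` (length-4 probability
#'   vector), `trans` (4x4 row-stochastic matrix), `counts` (raw
#'   dinucleotide counts).
#' @examples
#' m <- fit_markov1(c("ACAC"), pseudocount = 0)
#' m$trans["A", "C"]  # 1
#' @export
fit_markov1 <- function(seqs, pseudocount = 1) {
  if (length(seqs) == 0) stop("empty input")
  if (any(nchar(seqs) < 2)) stop("each sequence must have length >= 2")
  counts <- matrix(0L, 4, 4, dimnames = list(BASES, BASES))
  first <- stats::setNames(rep(0L, 4), BASES)
  for (s in seqs) {
    codes <- encode_bases(s)
    if (anyNA(codes)) stop("non-ACGT base in training sequence")
    if (!is.na(codes[1])) first[codes[1]] <- first[codes[1]] + 1L
    tab <- table(factor(codes[-length(codes)], levels = 1:4),
                 factor(codes[-1], levels = 1:4))
    counts <- counts + as.integer(tab)
  }
  ci <- counts + pseudocount
  fi <- first + pseudocount
  structure(
    list(initial = fi / sum(fi),
         trans = ci / rowSums(ci),
         counts = counts),
    class = "markov1_model")
}

#' @export
print.markov1_model <- function(x, ...) {
  cat("<markov1_model> initial:",
      paste(sprintf("%s=%.3f", BASES, x$initial), collapse = " "), "\n")
  invisible(x)
}

#' A neutral default background model
#'
#' Mildly GC-rich (42% AT / 58% GC-weighted steps would be extreme; this one
#' is near-uniform with a small CpG depletion), standing in for the
#' promoter-trained shuffle model when no training sequences are given.
#'
#' @return A `markov1_model`.
#' @export
default_markov1 <- function() {
  trans <- matrix(0.25, 4, 4, dimnames = list(BASES, BASES))
  trans["C", "G"] <- 0.10          # CpG depletion, the one strong human bias
  trans["C", ] <- trans["C", ] / sum(trans["C", ])
  structure(list(initial = stats::setNames(rep(0.25, 4), BASES),
                 trans = trans,
                 counts = matrix(NA_integer_, 4, 4,
                                 dimnames = list(BASES, BASES))),
            class = "markov1_model")
}

#' Generate background (non-promoter) sequences
#'
#' Samples `n` independent first-order Markov chains — the randomized
#' non-promoter set standing in for shuffled promoters.
#'
#' @param model a `markov1_model`.
#' @param n number of sequences.
#' @param length sequence length (default the 251-nt window).
#' @param seed RNG seed; fixed seed gives identical output.
#' @return Character vector of `n` sequences.
#' @export
generate_background <- function(model, n, length = 251, seed = NULL) {
  stopifnot(n > 0, length > 0)
  with_seed(seed, generate_background_impl(model, n, length))
}

generate_background_impl <- function(model, n, length) {
  codes <- matrix(0L, n, length)
  codes[, 1] <- sample.int(4, n, replace = TRUE, prob = model$initial)
  cum <- t(apply(model$trans, 1, cumsum))   # 4 x 4 cumulative rows
  if (length > 1) for (j in 2:length) {
    u <- stats::runif(n)
    # vectorized categorical draw conditioned on the previous base
    codes[, j] <- 1L + rowSums(u > cum[codes[, j - 1], , drop = FALSE])
  }
  apply(codes, 1, function(r) paste(BASES[r], collapse = ""))
}

#' Promoter simulation configuration
#'
#' The simulator plants a TATA-like box with its start at TSS-relative -30
#' and an Inr-like pyrimidine/purine element spanning the TSS (start -2, so
#' the canonical purine sits at +1 of the pyrimidine-purine step) on top of
#' Markov background chains. `plant_prob` is the per-element planting
#' probability: 1 gives a fully signalled positive set, 0 a null set
#' indistinguishable from the background.
#'
#' @param n number of sequences.
#' @param up,down window extent (length `up + down + 1`).
#' @param tata_motif,tata_pos TATA element and TSS-relative start.
#' @param inr_motif,inr_pos Inr element and TSS-relative start.
#' @param plant_prob per-element planting probability in `[0, 1]`.
#' @param background `markov1_model` for the backbone chains.
#' @param seed RNG seed.
#' @return A `promoter_sim_config` list.
#' @export
promoter_sim_config <- function(n, up = 200, down = 50,
                                tata_motif = "TATAAA", tata_pos = -30,
                                inr_motif = "TCAGTT", inr_pos = -2,
                                plant_prob = 1,
                                background = default_markov1(),
                                seed = NULL) {
  stopifnot(plant_prob >= 0, plant_prob <= 1, n > 0)
  for (el in list(c(tata_pos, nchar(tata_motif)), c(inr_pos, nchar(inr_motif))))
    if (el[1] < -up || el[1] + el[2] - 1 > down)
      stop("motif [", el[1], ", ", el[1] + el[2] - 1,
           "] does not fit in the window [-", up, ", ", down, "]")
  structure(list(n = n, up = up, down = down,
                 tata_motif = toupper(tata_motif), tata_pos = tata_pos,
                 inr_motif = toupper(inr_motif), inr_pos = inr_pos,
                 plant_prob = plant_prob, background = background,
                 seed = seed),
            class = "promoter_sim_config")
}

#' Simulate promoter-like sequences with planted core elements
#'
#' @param cfg a [promoter_sim_config()].
#' @return List with `sequences` (named character vector) and `manifest`
#'   (`data.frame` of planted elements: `id`, `element`, `start`, `end` in
#'   TSS-relative coordinates).
#' @export
generate_promoters <- function(cfg) {
  stopifnot(inherits(cfg, "promoter_sim_config"))
  with_seed(cfg$seed, generate_promoters_impl(cfg))
}

generate_promoters_impl <- function(cfg) {
  L <- cfg$up + cfg$down + 1
  seqs <- generate_background_impl(cfg$background, cfg$n, length = L)
  names(seqs) <- sprintf("prom%04d", seq_len(cfg$n))
  elements <- list(tata = c(cfg$tata_pos, nchar(cfg$tata_motif), 1),
                   inr = c(cfg$inr_pos, nchar(cfg$inr_motif), 2))
  motifs <- c(cfg$tata_motif, cfg$inr_motif)
  manifest <- list()
  for (el in names(elements)) {
    e <- elements[[el]]
    plant <- stats::runif(cfg$n) <= cfg$plant_prob
    if (!any(plant)) next
    i0 <- e[1] + cfg$up + 1          # window index of the motif start
    m <- motifs[e[3]]
    substr(seqs[plant], i0, i0 + e[2] - 1) <- m
    manifest[[el]] <- data.frame(id = names(seqs)[plant], element = el,
                                 start = e[1], end = e[1] + e[2] - 1)
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(id = character(), element = character(),
               start = integer(), end = integer())
  rownames(manifest) <- NULL
  list(sequences = seqs, manifest = manifest)
}

#' Simulate a full labeled promoter / non-promoter dataset
#'
#' Positives from [generate_promoters()], negatives from
#' [generate_background()] under the same Markov model, as a
#' [labeled_sequence_set()] ready for [build_matrix()].
#'
#' @param n_per_class sequences per class.
#' @param plant_prob per-element planting probability for the positives.
#' @param background `markov1_model`.
#' @param seed RNG seed driving both classes.
#' @param ... further arguments to [promoter_sim_config()].
#' @return List with `set` (labeled_sequence_set) and `manifest`.
#' @export
simulate_dataset <- function(n_per_class, plant_prob = 1,
                             background = default_markov1(),
                             seed = NULL, ...) {
  cfg <- promoter_sim_config(n = n_per_class, plant_prob = plant_prob,
                             background = background, seed = NULL, ...)
  L <- cfg$up + cfg$down + 1
  res <- with_seed(seed, {
    pos <- generate_promoters_impl(cfg)
    neg <- generate_background_impl(background, n_per_class, length = L)
    list(pos = pos, neg = neg)
  })
  pos <- res$pos
  neg <- res$neg
  names(neg) <- sprintf("bg%04d", seq_len(n_per_class))
  list(set = labeled_sequence_set(c(pos$sequences, neg),
                                  rep(c(TRUE, FALSE), each = n_per_class)),
       manifest = pos$manifest)
}

#' Write simulated sequences plus manifest sidecar
#'
#' @param sim result of [generate_promoters()].
#' @param path FASTA path; the manifest goes to `<path>.manifest.tsv`.
#' @export
write_simulation <- function(sim, path) {
  write_fasta(sim$sequences, path)
  utils::write.table(sim$manifest, paste0(path, ".manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
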