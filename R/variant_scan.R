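#' Enumerate wildtype/mutant peptide windows covering a point variant
#'
#' For every requested length `L`, emits every window of `L` consecutive
#' residues that lies fully inside the protein and contains the variant
#' position, paired with the same window carrying the single-residue
#' substitution. Windows are emitted in (length ascending, start ascending)
#' order. The protein sequence must agree with the variant's stated
#' reference residue.
#'
#' @param sequence protein sequence string.
#' @param variant one-row data.frame (or list) with `gene`, `position`,
#'   `ref_aa`, `alt_aa` (1-based position).
#' @param lengths integer vector of window lengths.
#' @return data.frame `length`, `start` (1-based), `wt_peptide`,
#'   `mut_peptide`.
#' @export
enumerate_variant_windows <- function(sequence, variant, lengths) {
  pos <- as.integer(variant$position)
  plen <- nchar(sequence)
  if (pos < 1L || pos > plen) {
    stop("variant ", variant$gene, " position ", pos,
         " outside protein of length ", plen, call. = FALSE)
  }
  ref <- substr(sequence, pos, pos)
  if (ref != variant$ref_aa) {
    stop("reference mismatch for ", variant$gene, " position ", pos,
         ": sequence has '", ref, "', variant table says '", variant$ref_aa,
         "'", call. = FALSE)
  }
  rows <- list()
  for (L in sort(unique(as.integer(lengths)))) {
    starts <- seq.int(max(1L, pos - L + 1L), min(pos, plen - L + 1L))
    starts <- starts[starts >= 1L & starts <= plen - L + 1L]
    if (length(starts) == 0L) next
    wt <- substr(rep(sequence, length(starts)), starts, starts + L - 1L)
    off <- pos - starts + 1L
    mut <- wt
    substr(mut, off, off) <- rep(variant$alt_aa, length(starts))
    rows[[as.character(L)]] <- data.frame(length = L, start = starts,
                                          wt_peptide = wt, mut_peptide = mut,
                                          stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(length = integer(0), start = integer(0),
                      wt_peptide = character(0), mut_peptide = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score all variant windows and flag kept mutant epitope candidates
#'
#' Implements the mutant-epitope screen: every (window, allele) pair is
#' ranked for both the wildtype and the mutant peptide, and a candidate is
#' *kept* when the mutant binds at least as strongly as the wildtype
#' (`mut_rank <= wt_rank`; set `strict = TRUE` to require a strictly lower
#' rank) **and** the mutant clears the class-specific strong-binder bound
#' (below 0.5 percent for class I, below 1 percent for class II by default).
#' The bound gates the mutant only; the wildtype rank is reported but not
#' gated. All candidates are returned with their flags so the filter is
#' auditable.
#'
#' @param sequence protein sequence string.
#' @param variant one-row variant as in [enumerate_variant_windows()].
#' @param models named list of [build_motif_model()] objects (classes may be
#'   mixed; each allele is scanned at its own class lengths).
#' @param calibrations named list of matching [calibrate_ranks()] objects.
#' @param lengths named list of window lengths per class; defaults to
#'   `list(I = 8:14, II = 15)` (class II may be widened to 11:20).
#' @param strong_bounds named numeric, strong-binder bound per class.
#' @param strict require `mut_rank < wt_rank` instead of `<=`.
#' @return data.frame of all candidates: variant fields, `allele`,
#'   `hla_class`, `length`, `start`, `wt_peptide`, `mut_peptide`, `wt_rank`,
#'   `mut_rank`, `kept`.
#' @export
scan_variant <- function(sequence, variant, models, calibrations,
                         lengths = list(I = 8:14, II = 15L),
                         strong_bounds = c(I = default_strong_bound("I"),
                                           II = default_strong_bound("II")),
                         strict = FALSE) {
  pieces <- list()
  for (al in names(models)) {
    cls <- models[[al]]$hla_class
    win <- enumerate_variant_windows(sequence, variant, lengths[[cls]])
    if (nrow(win) == 0L) next
    wt_rank <- percent_rank(calibrations[[al]],
                            score_peptides(models[[al]], win$wt_peptide),
                            win$length)
    mut_rank <- percent_rank(calibrations[[al]],
                             score_peptides(models[[al]], win$mut_peptide),
                             win$length)
    better <- if (strict) mut_rank < wt_rank else mut_rank <= wt_rank
    pieces[[al]] <- data.frame(gene = variant$gene,
                               protein_id = variant$protein_id %||% variant$gene,
                               position = as.integer(variant$position),
                               ref_aa = variant$ref_aa,
                               alt_aa = variant$alt_aa,
                               allele = al, hla_class = cls,
                               length = win$length, start = win$start,
                               wt_peptide = win$wt_peptide,
                               mut_peptide = win$mut_peptide,
                               wt_rank = wt_rank, mut_rank = mut_rank,
                               kept = better & mut_rank < strong_bounds[[cls]],
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), protein_id = character(0),
                      position = integer(0), ref_aa = character(0),
                      alt_aa = character(0), allele = character(0),
                      hla_class = character(0), length = integer(0),
                      start = integer(0), wt_peptide = character(0),
                      mut_peptide = character(0), wt_rank = numeric(0),
                      mut_rank = numeric(0), kept = logical(0))
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scan every variant of a table against a protein set
#'
#' Convenience wrapper running [scan_variant()] for each row of a variant
#' table, matching proteins by `protein_id` (falling back to `gene`).
#'
#' @param proteome data.frame with `protein_id`, `sequence`.
#' @param variants data.frame from [read_variant_table()] or
#'   [make_variant_fixture()].
#' @inheritParams scan_variant
#' @return row-bound candidate data.frame (see [scan_variant()]), with a
#'   `disease_label` column carried through untouched.
#' @export
scan_variants <- function(proteome, variants, models, calibrations,
                          lengths = list(I = 8:14, II = 15L),
                          strong_bounds = c(I = default_strong_bound("I"),
                                            II = default_strong_bound("II")),
                          strict = FALSE) {
  pieces <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    j <- match(v$protein_id, proteome$protein_id)
    if (is.na(j)) j <- match(v$gene, proteome$protein_id)
    if (is.na(j)) {
      stop("no protein sequence for variant ", v$gene, " (", v$protein_id,
           ")", call. = FALSE)
    }
    cand <- scan_variant(proteome$sequence[j], v, models, calibrations,
                         lengths, strong_bounds, strict)
    if (nrow(cand) > 0L) cand$disease_label <- v$disease_label %||% NA_character_
    pieces[[i]] <- cand
  }
  out <- do.call(rbind, pieces[lengths_nonzero(pieces)])
  if (is.null(out)) return(scan_variant_empty_with_label())
  rownames(out) <- NULL
  out
}

lengths_nonzero <- function(pieces) {
  vapply(pieces, function(p) !is.null(p) && nrow(p) > 0L, logical(1))
}

scan_variant_empty_with_label <- function() {
  out <- data.frame(gene = character(0), protein_id = character(0),
                    position = integer(0), ref_aa = character(0),
                    alt_aa = character(0), allele = character(0),
                    hla_class = character(0), length = integer(0),
                    start = integer(0), wt_peptide = character(0),
                    mut_peptide = character(0), wt_rank = numeric(0),
                    mut_rank = numeric(0), kept = logical(0),
                    disease_label = character(0))
  out
}

#' Summarise kept mutant epitopes per gene and allele
#'
#' Keeps only candidates that passed the filter, collapses duplicate mutant
#' peptides under the same allele to a single row (retaining the lowest
#' mutant rank, i.e. the best-scoring window register), and sorts each
#' (gene, allele) group by ascending mutant rank.
#'
#' @param candidates data.frame from [scan_variant()] / [scan_variants()].
#' @return data.frame `gene`, `allele`, `hla_class`, `mut_peptide`,
#'   `wt_peptide`, `mut_rank`, `wt_rank` (plus `disease_label` when present).
#' @export
summarize_scan <- function(candidates) {
  kept <- candidates[candidates$kept, , drop = FALSE]
  cols <- intersect(c("gene", "allele", "hla_class", "mut_peptide",
                      "wt_peptide", "mut_rank", "wt_rank", "disease_label"),
                    names(kept))
  if (nrow(kept) == 0L) {
    out <- kept[, cols, drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  kept <- kept[order(kept$gene, kept$allele, kept$mut_rank, kept$wt_rank), ]
  dup <- duplicated(kept[, c("allele", "mut_peptide")])
  out <- kept[!dup, cols, drop = FALSE]
  rownames(out) <- NULL
  out
}
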