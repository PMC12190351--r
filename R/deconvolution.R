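#' Default deconvolution rank cutoff per class
#'
#' Stringent filtering retains peptides with percentile rank below 2 for
#' class I and below 5 for class II.
#'
#' @param hla_class `"I"` or `"II"`.
#' @return numeric cutoff on the percent scale.
#' @export
default_rank_cutoff <- function(hla_class) {
  switch(match.arg(hla_class, c("I", "II")), I = 2, II = 5)
}

#' Default strong-binder rank bound per class
#'
#' Strong binders are peptides below rank 0.5 for class I and below 1 for
#' class II.
#'
#' @param hla_class `"I"` or `"II"`.
#' @return numeric bound on the percent scale.
#' @export
default_strong_bound <- function(hla_class) {
  switch(match.arg(hla_class, c("I", "II")), I = 0.5, II = 1)
}

#' Classify a percentile rank into binder classes
#'
#' Class I: strong below 0.5, weak in \[0.5, 2), else non-binder. Class II:
#' strong below 1, weak in \[1, 5), else non-binder. All boundaries are
#' exclusive for the stronger class (the cutoffs are stated as strict
#' "below" thresholds).
#'
#' @param rank numeric vector of ranks in (0, 100].
#' @param hla_class `"I"` or `"II"`.
#' @return character vector: `"strong"`, `"weak"` or `"non"`.
#' @export
classify_binder <- function(rank, hla_class) {
  strong <- default_strong_bound(hla_class)
  weak <- default_rank_cutoff(hla_class)
  ifelse(rank < strong, "strong", ifelse(rank < weak, "weak", "non"))
}

#' Assign detected peptides to their best allele by minimum rank
#'
#' Deduplicates the peptide list by sequence (assignment is a property of the
#' sequence, not of the sample it was detected in), drops peptides outside
#' the class length window with a reported count, ranks every remaining
#' peptide against every allele, and assigns each to the allele of minimum
#' rank (ties broken toward the lexicographically smallest allele name). A
#' peptide is *retained* when its best rank is strictly below the
#' class-specific cutoff.
#'
#' @param peptides character vector of sequences, or a data.frame with a
#'   `sequence` column (as from [read_peptide_list()]).
#' @param models named list of [build_motif_model()] objects, one per
#'   allele, all of the same class.
#' @param calibrations named list of matching [calibrate_ranks()] objects.
#' @param rank_cutoff retention cutoff in percent; defaults to
#'   [default_rank_cutoff()] for the class.
#' @param rank_fun optional predictor adapter: a
#'   `function(peptides, allele)` returning percentile ranks, substituting
#'   for the built-in PSSM + calibration route (e.g. wrapping an external
#'   predictor executable). Models are still consulted for the class label.
#' @return data.frame with one row per distinct in-window peptide: `peptide`,
#'   `length`, `hla_class`, per-allele `rank_<allele>` columns, `best_allele`,
#'   `best_rank`, `binder_class`, `retained`; attribute `n_skipped` counts
#'   peptides outside the class window.
#' @export
deconvolute <- function(peptides, models, calibrations = NULL,
                        rank_cutoff = NULL, rank_fun = NULL) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  if (length(models) == 0L) stop("empty allele set", call. = FALSE)
  classes <- unique(vapply(models, `[[`, character(1), "hla_class"))
  if (length(classes) != 1L) {
    stop("all alleles in one deconvolution must share an HLA class",
         call. = FALSE)
  }
  hla_class <- classes
  if (is.null(rank_cutoff)) rank_cutoff <- default_rank_cutoff(hla_class)
  alleles <- sort(names(models))
  peps <- unique(peptides)
  window <- class_length_window(hla_class)
  in_window <- nchar(peps) %in% window
  n_skipped <- sum(!in_window)
  if (n_skipped > 0L) {
    message(n_skipped, " peptide(s) outside the class ", hla_class,
            " length window skipped")
  }
  peps <- peps[in_window]
  ranks <- matrix(NA_real_, nrow = length(peps), ncol = length(alleles),
                  dimnames = list(NULL, alleles))
  for (al in alleles) {
    ranks[, al] <- if (!is.null(rank_fun)) {
      rank_fun(peps, al)
    } else {
      percent_rank(calibrations[[al]], score_peptides(models[[al]], peps),
                   nchar(peps))
    }
  }
  if (length(peps) == 0L) {
    out <- data.frame(peptide = character(0), length = integer(0),
                      hla_class = character(0), best_allele = character(0),
                      best_rank = numeric(0), binder_class = character(0),
                      retained = logical(0))
  } else {
    best_j <- apply(ranks, 1L, which.min)  # first minimum = smallest name
    best_rank <- ranks[cbind(seq_along(peps), best_j)]
    out <- data.frame(peptide = peps, length = nchar(peps),
                      hla_class = hla_class, stringsAsFactors = FALSE)
    for (al in alleles) out[[paste0("rank_", al)]] <- ranks[, al]
    out$best_allele <- alleles[best_j]
    out$best_rank <- best_rank
    out$binder_class <- classify_binder(best_rank, hla_class)
    out$retained <- best_rank < rank_cutoff
  }
  attr(out, "n_skipped") <- n_skipped
  attr(out, "rank_cutoff") <- rank_cutoff
  out
}

#' Peptide length histogram of assignments
#'
#' @param assignments data.frame from [deconvolute()].
#' @param retained_only count only retained assignments (default `TRUE`).
#' @return named integer vector, names = observed lengths ascending; empty
#'   input gives an empty histogram.
#' @export
length_distribution <- function(assignments, retained_only = TRUE) {
  x <- if (retained_only) assignments[assignments$retained, ] else assignments
  if (nrow(x) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(x$length)
  stats::setNames(as.integer(tab), names(tab))
}

#' Top-ranked retained epitopes per allele
#'
#' @param assignments data.frame from [deconvolute()].
#' @param n number of epitopes per allele (>= 1); alleles with fewer retained
#'   peptides return what they have.
#' @return data.frame `allele`, `peptide`, `best_rank`, `binder_class`,
#'   sorted by allele then ascending rank (ties by peptide lexicographic
#'   order).
#' @export
top_epitopes_per_allele <- function(assignments, n = 3L) {
  stopifnot(n >= 1L)
  x <- assignments[assignments$retained, , drop = FALSE]
  pieces <- lapply(split(x, x$best_allele), function(d) {
    d <- d[order(d$best_rank, d$peptide), , drop = FALSE]
    utils::head(d, n)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    return(data.frame(allele = character(0), peptide = character(0),
                      best_rank = numeric(0), binder_class = character(0)))
  }
  res <- data.frame(allele = out$best_allele, peptide = out$peptide,
                    best_rank = out$best_rank,
                    binder_class = out$binder_class,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Two-set overlap summary with whole-percent shares
#'
#' Counts the shared and unique identifiers of two sets and expresses each
#' count as a percentage of the union, rounded half-up to the nearest whole
#' percent (so the printed shares need not sum to exactly 100).
#'
#' @param set_a,set_b vectors of identifiers (duplicates ignored).
#' @return list with `shared`, `unique_a`, `unique_b`, `union_size`,
#'   `shared_pct`, `unique_a_pct`, `unique_b_pct`.
#' @export
overlap_summary <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  shared <- length(intersect(a, b))
  ua <- length(setdiff(a, b))
  ub <- length(setdiff(b, a))
  u <- shared + ua + ub
  pct <- function(k) if (u == 0L) 0 else round_half_up(100 * k / u)
  list(shared = shared, unique_a = ua, unique_b = ub, union_size = u,
       shared_pct = pct(shared), unique_a_pct = pct(ua),
       unique_b_pct = pct(ub))
}

#' @rdname overlap_summary
#' @param counts alternative entry point: precomputed counts
#'   `c(shared, unique_a, unique_b)` when only the tallies (not the sets) are
#'   available, as in a published Venn diagram.
#' @export
overlap_summary_counts <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  u <- sum(counts)
  pct <- function(k) if (u == 0L) 0 else round_half_up(100 * k / u)
  list(shared = counts[[1L]], unique_a = counts[[2L]],
       unique_b = counts[[3L]], union_size = u,
       shared_pct = pct(counts[[1L]]), unique_a_pct = pct(counts[[2L]]),
       unique_b_pct = pct(counts[[3L]]))
}

#' Filter a reported epitope table at a rank cutoff
#'
#' Retains rows whose printed eluted-ligand rank is less than or equal to the
#' cutoff. Unlike [deconvolute()] (which filters raw ranks strictly), the
#' comparison here is inclusive: printed table ranks are already-rounded
#' reported values, so a row printed exactly at the boundary is retained.
#'
#' @param rows data.frame with `gene` and `el_rank_percent` columns (e.g.
#'   from [load_table1_fixture()]).
#' @param rank_cutoff cutoff in percent.
#' @return list with `rows` (the retained data.frame), `n_retained`, and
#'   `n_genes` (distinct gene symbols among retained rows).
#' @export
filter_epitope_table <- function(rows, rank_cutoff) {
  keep <- rows[rows$el_rank_percent <= rank_cutoff, , drop = FALSE]
  rownames(keep) <- NULL
  list(rows = keep, n_retained = nrow(keep),
       n_genes = length(unique(keep$gene)))
}
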