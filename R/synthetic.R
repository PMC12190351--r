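#' Default peptide length weights per HLA class
#'
#' Class I weights cover 8-14-mers with the mode at 9; class II weights cover
#' 11-20-mers with the mode at 15, matching the canonical binding-groove
#' geometry (closed class I groove, open-ended class II groove) and the
#' length distributions observed in eluted-ligand data. Values are fixed
#' package defaults, not fitted quantities.
#'
#' @param hla_class `"I"` or `"II"`.
#' @return named numeric vector (names = lengths) summing to 1.
#' @export
default_length_weights <- function(hla_class) {
  switch(match.arg(hla_class, c("I", "II")),
    I  = c(`8` = 0.10, `9` = 0.45, `10` = 0.18, `11` = 0.12, `12` = 0.07,
           `13` = 0.05, `14` = 0.03),
    II = c(`11` = 0.04, `12` = 0.06, `13` = 0.09, `14` = 0.14, `15` = 0.24,
           `16` = 0.15, `17` = 0.11, `18` = 0.08, `19` = 0.05, `20` = 0.04))
}

#' Allowed peptide length window per HLA class
#'
#' @param hla_class `"I"` or `"II"`.
#' @return integer vector of allowed lengths (8-14 for class I, 11-20 for
#'   class II).
#' @export
class_length_window <- function(hla_class) {
  switch(match.arg(hla_class, c("I", "II")), I = 8:14, II = 11:20)
}

#' Specify a synthetic ligandome
#'
#' Bundles every knob of the generator into one validated object so that a
#' simulation is fully described by the spec plus nothing else. All alleles
#' in one spec share an HLA class, mirroring the wet-lab workflow in which
#' class I and class II ligandomes are immunoprecipitated and searched
#' separately.
#'
#' @param alleles character vector of allele names.
#' @param hla_class `"I"` or `"II"`.
#' @param anchor_positions integer vector of core positions (1-9) carrying a
#'   concentrated residue preference; recycled to every allele. Defaults to
#'   the canonical pockets: positions 2 and 9 for class I, 1, 4 and 9 for the
#'   class II core.
#' @param anchor_residues optional named list (by allele) of preferred
#'   residues, one per anchor position; when `NULL` they are drawn
#'   deterministically from the allele's child random stream.
#' @param motif_sharpness probability mass placed on the preferred residue at
#'   each anchor, in (0, 1].
#' @param length_weights named numeric vector mapping peptide length to
#'   sampling probability; must sum to 1 and stay inside the class window.
#' @param n_ligands_per_allele positive integer.
#' @param decoy_fraction fraction of all emitted peptides that are
#'   background-drawn decoys, in \[0, 1).
#' @param seed integer master seed; every allele and the decoy block consume
#'   an independent child stream derived from it, so adding an allele never
#'   perturbs another allele's sample.
#' @return object of class `"ligandome_spec"`.
#' @export
ligandome_spec <- function(alleles, hla_class = "I",
                           anchor_positions = NULL,
                           anchor_residues = NULL,
                           motif_sharpness = 0.8,
                           length_weights = NULL,
                           n_ligands_per_allele = 1000L,
                           decoy_fraction = 0.2,
                           seed = 1L) {
  hla_class <- match.arg(hla_class, c("I", "II"))
  stopifnot(length(alleles) >= 1L, !anyDuplicated(alleles))
  if (is.null(anchor_positions)) {
    anchor_positions <- if (hla_class == "I") c(2L, 9L) else c(1L, 4L, 9L)
  }
  stopifnot(all(anchor_positions >= 1L), all(anchor_positions <= 9L),
            !anyDuplicated(anchor_positions))
  if (is.null(length_weights)) length_weights <- default_length_weights(hla_class)
  lens <- as.integer(names(length_weights))
  window <- class_length_window(hla_class)
  if (any(is.na(lens)) || !all(lens %in% window)) {
    stop("length_weights must be named by lengths inside the class ",
         hla_class, " window [", min(window), ", ", max(window), "]",
         call. = FALSE)
  }
  if (abs(sum(length_weights) - 1) > 1e-8) {
    stop("length_weights must sum to 1", call. = FALSE)
  }
  stopifnot(motif_sharpness > 0, motif_sharpness <= 1,
            n_ligands_per_allele >= 1L,
            decoy_fraction >= 0, decoy_fraction < 1,
            is.numeric(seed), length(seed) == 1L)
  structure(list(alleles = as.character(alleles), hla_class = hla_class,
                 anchor_positions = as.integer(anchor_positions),
                 anchor_residues = anchor_residues,
                 motif_sharpness = motif_sharpness,
                 length_weights = length_weights,
                 n_ligands_per_allele = as.integer(n_ligands_per_allele),
                 decoy_fraction = decoy_fraction,
                 seed = as.integer(seed)),
            class = "ligandome_spec")
}

#' @export
print.ligandome_spec <- function(x, ...) {
  cat("Synthetic ligandome spec: ", length(x$alleles), " class ", x$hla_class,
      " allele(s), ", x$n_ligands_per_allele, " ligands/allele, decoy fraction ",
      x$decoy_fraction, ", sharpness ", x$motif_sharpness, ", seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Build ground-truth motif matrices for a synthetic spec
#'
#' For each allele, constructs a 9 x 20 position-probability matrix over the
#' binding core. Anchor columns put `motif_sharpness` mass on that allele's
#' preferred residue and spread the remainder over the other 19 residues in
#' proportion to the background; non-anchor columns are a mild Dirichlet
#' perturbation of the background (concentration 500), so they carry little
#' information. Each allele's matrix is drawn from its own child stream and
#' is bitwise reproducible from the spec.
#'
#' @param spec a [ligandome_spec()].
#' @return named list of matrices (rows = core positions 1-9, columns =
#'   [aa_alphabet()]), each with attributes `anchor_positions` and
#'   `anchor_residues`.
#' @export
make_allele_motifs <- function(spec) {
  stopifnot(inherits(spec, "ligandome_spec"))
  aa <- aa_alphabet()
  bg <- background_frequencies()
  out <- vector("list", length(spec$alleles))
  names(out) <- spec$alleles
  for (al in spec$alleles) {
    set.seed(derive_seed(spec$seed, paste0("motif/", al)))
    prefs <- spec$anchor_residues[[al]]
    if (is.null(prefs)) {
      # deterministic draw from the child stream; restrict to residues rare
      # enough in the background (< 5%) that the anchor is informative, the
      # way real groove pockets prefer distinctive side chains
      eligible <- aa[bg < min(0.05, spec$motif_sharpness)]
      prefs <- sample(eligible, length(spec$anchor_positions), replace = FALSE)
    }
    if (length(prefs) != length(spec$anchor_positions)) {
      stop("need one preferred residue per anchor position for allele ", al,
           call. = FALSE)
    }
    if (any(spec$motif_sharpness <= bg[prefs])) {
      stop("motif_sharpness ", spec$motif_sharpness, " <= background ",
           "frequency of preferred residue for allele ", al,
           "; motif would be uninformative", call. = FALSE)
    }
    m <- matrix(NA_real_, nrow = 9L, ncol = 20L, dimnames = list(NULL, aa))
    for (j in seq_len(9L)) {
      k <- match(j, spec$anchor_positions)
      if (!is.na(k)) {
        pref <- prefs[k]
        col <- bg
        col[pref] <- 0
        col <- col / sum(col) * (1 - spec$motif_sharpness)
        col[pref] <- spec$motif_sharpness
        m[j, ] <- col
      } else {
        g <- stats::rgamma(20L, shape = bg * 500)
        m[j, ] <- g / sum(g)
      }
    }
    attr(m, "anchor_positions") <- spec$anchor_positions
    attr(m, "anchor_residues") <- prefs
    out[[al]] <- m
  }
  out
}

#' Sample a synthetic ligandome with truth labels
#'
#' For each allele, draws `n_ligands_per_allele` peptides: a 9-residue core
#' sampled column-wise from the allele's motif matrix, extended to the
#' sampled length. Class I peptides are built by the inverse of the scoring
#' core-mapping rule (8-mers drop the central core position; longer peptides
#' insert background residues after core position 5), so that core-mapping a
#' ligand recovers its motif positions. Class II peptides place the core at a
#' uniformly drawn offset and fill both flanks from the background. Decoys
#' are drawn i.i.d. from the background with uniform length over the class
#' window; `decoy_fraction` is the decoy share of all emitted peptides, so
#' `n_decoys = round(decoy_fraction / (1 - decoy_fraction) * n_ligands)`.
#'
#' @param spec a [ligandome_spec()].
#' @param motifs matrices from [make_allele_motifs()] (rebuilt from `spec`
#'   when omitted).
#' @return list with `peptides` (data.frame `sequence`, `sample_id`,
#'   `intensity`) and `truth` (data.frame `sequence`, `label`), row-aligned;
#'   `label` is the generating allele name or `"decoy"`.
#' @export
sample_ligandome <- function(spec, motifs = make_allele_motifs(spec)) {
  stopifnot(inherits(spec, "ligandome_spec"))
  force(motifs)  # must be realised before any child stream is seeded
  if (length(spec$alleles) == 0L) stop("empty allele set", call. = FALSE)
  aa <- aa_alphabet()
  bg <- background_frequencies()
  lens <- as.integer(names(spec$length_weights))
  seq_list <- list()
  lab_list <- list()
  for (al in spec$alleles) {
    set.seed(derive_seed(spec$seed, paste0("ligands/", al)))
    n <- spec$n_ligands_per_allele
    L <- lens[sample.int(length(lens), n, replace = TRUE,
                         prob = spec$length_weights)]
    m <- motifs[[al]]
    cores <- matrix("", nrow = n, ncol = 9L)
    for (j in seq_len(9L)) {
      cores[, j] <- sample(aa, n, replace = TRUE, prob = m[j, ])
    }
    peps <- character(n)
    for (i in seq_len(n)) {
      peps[i] <- if (spec$hla_class == "I") {
        assemble_class1(cores[i, ], L[i], aa, bg)
      } else {
        assemble_class2(cores[i, ], L[i], aa, bg)
      }
    }
    seq_list[[al]] <- peps
    lab_list[[al]] <- rep(al, n)
  }
  n_lig <- sum(lengths(seq_list))
  n_decoy <- round(spec$decoy_fraction / (1 - spec$decoy_fraction) * n_lig)
  if (n_decoy > 0L) {
    set.seed(derive_seed(spec$seed, "decoys"))
    window <- class_length_window(spec$hla_class)
    Ld <- window[sample.int(length(window), n_decoy, replace = TRUE)]
    seq_list[["decoy"]] <- vapply(Ld, function(l) {
      paste(sample(aa, l, replace = TRUE, prob = bg), collapse = "")
    }, character(1))
    lab_list[["decoy"]] <- rep("decoy", n_decoy)
  }
  sequences <- unlist(seq_list, use.names = FALSE)
  labels <- unlist(lab_list, use.names = FALSE)
  list(peptides = data.frame(sequence = sequences,
                             sample_id = "synthetic",
                             intensity = NA_real_,
                             stringsAsFactors = FALSE),
       truth = data.frame(sequence = sequences, label = labels,
                          stringsAsFactors = FALSE))
}

# class I assembly: inverse of map_to_core (core position 5 is the flexible
# central bulge); calls into the sampler's active RNG stream
assemble_class1 <- function(core, L, aa, bg) {
  if (L == 8L) {
    paste(core[-5L], collapse = "")
  } else if (L == 9L) {
    paste(core, collapse = "")
  } else {
    ins <- sample(aa, L - 9L, replace = TRUE, prob = bg)
    paste(c(core[1:5], ins, core[6:9]), collapse = "")
  }
}

# class II assembly: 9-mer core at a uniform offset, background flanks
assemble_class2 <- function(core, L, aa, bg) {
  n_flank <- L - 9L
  left <- sample.int(n_flank + 1L, 1L) - 1L
  flanks <- sample(aa, n_flank, replace = TRUE, prob = bg)
  paste(c(if (left > 0L) flanks[seq_len(left)], core,
          if (left < n_flank) flanks[(left + 1L):n_flank]), collapse = "")
}

#' Sample a synthetic background proteome
#'
#' Protein sequences drawn i.i.d. from [background_frequencies()], with
#' lengths Poisson-distributed around `mean_length` (floored at 20 residues
#' so every protein can host at least one scoring window).
#'
#' @param n_proteins number of proteins (>= 1).
#' @param mean_length expected protein length in residues.
#' @param seed integer seed; the output is bitwise reproducible.
#' @return data.frame with `protein_id` (`SYNP0001`, ...) and `sequence`.
#' @export
sample_background_proteome <- function(n_proteins, mean_length = 350L,
                                       seed = 1L) {
  stopifnot(n_proteins >= 1L, mean_length >= 20L)
  set.seed(derive_seed(seed, "background_proteome"))
  aa <- aa_alphabet()
  bg <- background_frequencies()
  lens <- pmax(20L, stats::rpois(n_proteins, mean_length))
  seqs <- vapply(lens, function(l) {
    paste(sample(aa, l, replace = TRUE, prob = bg), collapse = "")
  }, character(1))
  data.frame(protein_id = sprintf("SYNP%04d", seq_len(n_proteins)),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Generate a synthetic point-variant table
#'
#' Samples `n_variants` single-residue substitutions at uniform positions of
#' a proteome, with `alt_aa != ref_aa`. When ground-truth motifs are given, a
#' fraction of the variants are *planted*: the generator searches for a
#' fully contained 9-mer window whose other anchor positions already carry
#' the motif's preferred residues, and substitutes the preferred residue at
#' the one remaining mismatched anchor. The mutant window then matches every
#' anchor of the generating motif, so it is guaranteed to outscore its
#' wildtype counterpart and (anchors being background-rare residues) to land
#' inside the strong-binder rank bound — giving downstream scans known true
#' positives. Planted rows are flagged in `disease_label` as
#' `synthetic_planted:<allele>`; if no such window exists after a bounded
#' search the planting falls back to a single-anchor substitution, flagged
#' `synthetic_planted_weak:<allele>`.
#'
#' @param proteome data.frame from [sample_background_proteome()] or
#'   [read_fasta()].
#' @param n_variants number of variants.
#' @param seed integer seed.
#' @param motifs optional motif list from [make_allele_motifs()].
#' @param planted_fraction fraction of variants to plant when `motifs` is
#'   supplied.
#' @return data.frame in [read_variant_table()] layout; `gene` is the
#'   protein identifier.
#' @export
make_variant_fixture <- function(proteome, n_variants, seed = 1L,
                                 motifs = NULL, planted_fraction = 0.5) {
  stopifnot(nrow(proteome) >= 1L, n_variants >= 1L)
  set.seed(derive_seed(seed, "variant_fixture"))
  aa <- aa_alphabet()
  n_planted <- if (is.null(motifs)) 0L else ceiling(n_variants * planted_fraction)
  rows <- vector("list", n_variants)
  for (i in seq_len(n_variants)) {
    rows[[i]] <- if (i <= n_planted) {
      plant_anchor_variant(proteome, motifs, aa)
    } else {
      p <- sample.int(nrow(proteome), 1L)
      plen <- nchar(proteome$sequence[p])
      pos <- sample.int(plen, 1L)
      ref <- substr(proteome$sequence[p], pos, pos)
      data.frame(gene = proteome$protein_id[p],
                 protein_id = proteome$protein_id[p],
                 position = pos, ref_aa = ref,
                 alt_aa = sample(setdiff(aa, ref), 1L),
                 disease_label = "synthetic", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_variants(out)
}

# search for a window whose other anchors already match the motif, and plant
# the preferred residue at the one mismatched anchor; consumes the caller's
# active RNG stream
plant_anchor_variant <- function(proteome, motifs, aa, max_tries = 500L) {
  for (try in seq_len(max_tries)) {
    al <- sample(names(motifs), 1L)
    anchors <- attr(motifs[[al]], "anchor_positions")
    prefs <- attr(motifs[[al]], "anchor_residues")
    k <- sample.int(length(anchors), 1L)
    p <- sample.int(nrow(proteome), 1L)
    seq_p <- proteome$sequence[p]
    plen <- nchar(seq_p)
    if (plen < 9L) next
    starts <- seq_len(plen - 9L + 1L)
    ok <- rep(TRUE, length(starts))
    for (j in seq_along(anchors)) {
      at <- substring(seq_p, starts + anchors[j] - 1L, starts + anchors[j] - 1L)
      ok <- ok & (if (j == k) at != prefs[j] else at == prefs[j])
    }
    if (!any(ok)) next
    start <- starts[ok][sample.int(sum(ok), 1L)]
    pos <- start + anchors[k] - 1L
    return(data.frame(gene = proteome$protein_id[p],
                      protein_id = proteome$protein_id[p],
                      position = pos,
                      ref_aa = substr(seq_p, pos, pos),
                      alt_aa = prefs[k],
                      disease_label = paste0("synthetic_planted:", al),
                      stringsAsFactors = FALSE))
  }
  # fallback: single-anchor planting without context (weak true positive)
  repeat {
    al <- sample(names(motifs), 1L)
    anchors <- attr(motifs[[al]], "anchor_positions")
    prefs <- attr(motifs[[al]], "anchor_residues")
    k <- sample.int(length(anchors), 1L)
    p <- sample.int(nrow(proteome), 1L)
    plen <- nchar(proteome$sequence[p])
    if (plen < 9L) next
    start <- sample.int(plen - 9L + 1L, 1L)
    pos <- start + anchors[k] - 1L
    ref <- substr(proteome$sequence[p], pos, pos)
    if (ref == prefs[k]) next
    return(data.frame(gene = proteome$protein_id[p],
                      protein_id = proteome$protein_id[p],
                      position = pos, ref_aa = ref, alt_aa = prefs[k],
                      disease_label = paste0("synthetic_planted_weak:", al),
                      stringsAsFactors = FALSE))
  }
}
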