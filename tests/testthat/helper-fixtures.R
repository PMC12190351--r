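# Shared synthetic fixtures, built once per test session and memoised.
# Seeds are fixed design choices of the test world, not tuned values.

.fix_env <- new.env(parent = emptyenv())

fix_memo <- function(key, expr) {
  if (!exists(key, envir = .fix_env, inherits = FALSE)) {
    assign(key, force(expr), envir = .fix_env)
  }
  get(key, envir = .fix_env, inherits = FALSE)
}

# background proteome shared by most calibrations
fix_background <- function() {
  fix_memo("background", sample_background_proteome(120, 350, seed = 202))
}

# two-allele class I world: sharpness 0.9, disjoint anchor residues,
# 500 ligands/allele, decoy fraction 0.2 (the assignment-recovery fixture)
fix_class1 <- function() {
  fix_memo("class1", {
    spec <- ligandome_spec(
      alleles = c("HLA-A01:01", "HLA-A11:01"), hla_class = "I",
      anchor_residues = list("HLA-A01:01" = c("Y", "W"),
                             "HLA-A11:01" = c("F", "K")),
      motif_sharpness = 0.9, n_ligands_per_allele = 500L,
      decoy_fraction = 0.2, seed = 301L)
    motifs <- make_allele_motifs(spec)
    lig <- sample_ligandome(spec, motifs)
    train_spec <- spec
    train_spec$seed <- 302L
    train <- sample_ligandome(train_spec, motifs)
    models <- lapply(stats::setNames(spec$alleles, spec$alleles), function(a) {
      build_motif_model(train$peptides$sequence[train$truth$label == a],
                        a, "I")
    })
    calibrations <- lapply(models, calibrate_ranks,
                           proteome = fix_background(), M = 3000L, seed = 303L)
    list(spec = spec, motifs = motifs, ligandome = lig,
         models = models, calibrations = calibrations)
  })
}

fix_class1_assignments <- function() {
  fix_memo("class1_assignments", {
    f <- fix_class1()
    deconvolute(f$ligandome$peptides, f$models, f$calibrations)
  })
}

# truth label per distinct peptide sequence (collisions: first label wins)
truth_lookup <- function(truth) {
  keep <- !duplicated(truth$sequence)
  stats::setNames(truth$label[keep], truth$sequence[keep])
}

# small class II world for training/scanning tests
fix_class2 <- function() {
  fix_memo("class2", {
    spec <- ligandome_spec(
      alleles = c("HLA-DRB1:0101", "HLA-DRB1:0404"), hla_class = "II",
      anchor_residues = list("HLA-DRB1:0101" = c("Y", "M", "K"),
                             "HLA-DRB1:0404" = c("F", "Q", "W")),
      motif_sharpness = 0.8, n_ligands_per_allele = 400L,
      decoy_fraction = 0.2, seed = 311L)
    motifs <- make_allele_motifs(spec)
    lig <- sample_ligandome(spec, motifs)
    models <- lapply(stats::setNames(spec$alleles, spec$alleles), function(a) {
      build_motif_model(lig$peptides$sequence[lig$truth$label == a], a, "II")
    })
    calibrations <- lapply(models, calibrate_ranks,
                           proteome = fix_background(), M = 3000L, seed = 312L)
    list(spec = spec, motifs = motifs, ligandome = lig,
         models = models, calibrations = calibrations)
  })
}

# wrap a ground-truth motif probability matrix as a scoring model
model_from_motif <- function(motif, allele, hla_class = "I",
                             background = background_frequencies()) {
  structure(list(allele = allele, hla_class = hla_class, core_length = 9L,
                 log_odds = log2(sweep(motif, 2L, background, "/")),
                 beta = 0, background = background, n_training_ligands = 0L),
            class = "AlleleMotifModel")
}

# hand calibration object over an explicit background score array
manual_calibration <- function(scores, length = 9L, allele = "TOY",
                               hla_class = "I") {
  structure(list(allele = allele, hla_class = hla_class,
                 lengths = as.integer(length),
                 scores = stats::setNames(list(sort(scores)),
                                          as.character(length)),
                 M = stats::setNames(base::length(scores), as.character(length)),
                 source = "manual", seed = 0L),
            class = "RankCalibration")
}

# brute-force oracle: every substring of every length containing the position
brute_force_windows <- function(sequence, pos, lengths) {
  out <- list()
  for (L in sort(unique(as.integer(lengths)))) {
    for (start in seq_len(max(0L, nchar(sequence) - L + 1L))) {
      if (pos >= start && pos <= start + L - 1L) {
        out[[length(out) + 1L]] <- data.frame(
          length = L, start = start,
          wt_peptide = substr(sequence, start, start + L - 1L))
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(length = integer(0), start = integer(0),
                      wt_peptide = character(0)))
  }
  do.call(rbind, out)
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(aa_alphabet(), n, replace = TRUE,
               prob = background_frequencies()), collapse = "")
}
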