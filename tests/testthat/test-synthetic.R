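test_that("motif matrices have the stated anchor structure", {
  spec <- ligandome_spec("AL", "I", anchor_positions = 2L,
                         anchor_residues = list(AL = "K"),
                         motif_sharpness = 0.7, seed = 5)
  m <- make_allele_motifs(spec)$AL
  expect_equal(dim(m), c(9L, 20L))
  expect_equal(unname(rowSums(m)), rep(1, 9), tolerance = 1e-12)
  # anchor column: max mass is the sharpness, on the preferred residue
  expect_equal(max(m[2L, ]), 0.7)
  expect_identical(names(which.max(m[2L, ])), "K")
  # non-anchor columns stay close to background (mild perturbation)
  bg <- background_frequencies()
  expect_lt(max(abs(m[5L, ] - bg)), 0.05)

  # degenerate sharpness: point mass
  spec1 <- ligandome_spec("AL", "I", anchor_positions = 2L,
                          anchor_residues = list(AL = "K"),
                          motif_sharpness = 1, seed = 5)
  m1 <- make_allele_motifs(spec1)$AL
  expect_equal(unname(m1[2L, "K"]), 1)
  expect_equal(sum(m1[2L, ] > 0), 1L)
})

test_that("motif generation is deterministic and rejects uninformative anchors", {
  spec <- ligandome_spec(c("A1", "A2"), "I", seed = 42)
  expect_identical(make_allele_motifs(spec), make_allele_motifs(spec))

  weak <- ligandome_spec("AL", "I", anchor_residues = list(AL = c("L", "K")),
                         motif_sharpness = 0.05, seed = 1)
  expect_error(make_allele_motifs(weak), "uninformative")
})

test_that("ligandome sampling conserves counts and length constraints", {
  spec <- ligandome_spec(c("A1", "A2"), "I", n_ligands_per_allele = 100L,
                         decoy_fraction = 0, seed = 7)
  lig <- sample_ligandome(spec)
  expect_equal(nrow(lig$peptides), 200L)

  nine <- ligandome_spec("A1", "I", length_weights = c(`9` = 1),
                         n_ligands_per_allele = 50L, decoy_fraction = 0,
                         seed = 7)
  expect_true(all(nchar(sample_ligandome(nine)$peptides$sequence) == 9L))

  half <- ligandome_spec("A1", "I", n_ligands_per_allele = 100L,
                         decoy_fraction = 0.5, seed = 7)
  lig2 <- sample_ligandome(half)
  expect_equal(nrow(lig2$peptides), 200L)
  expect_equal(sum(lig2$truth$label == "decoy"), 100L)
})

test_that("truth labels partition the emitted peptides", {
  spec <- ligandome_spec(c("A1", "A2"), "I", n_ligands_per_allele = 60L,
                         decoy_fraction = 0.25, seed = 13)
  lig <- sample_ligandome(spec)
  expect_equal(nrow(lig$truth), nrow(lig$peptides))
  expect_identical(lig$truth$sequence, lig$peptides$sequence)
  expect_setequal(unique(lig$truth$label), c("A1", "A2", "decoy"))
})

test_that("generation is bitwise reproducible and per-allele streams are independent", {
  spec <- ligandome_spec(c("A1", "A2"), "I", n_ligands_per_allele = 50L,
                         decoy_fraction = 0.2, seed = 99)
  expect_identical(sample_ligandome(spec), sample_ligandome(spec))

  wider <- ligandome_spec(c("A1", "A2", "A3"), "I",
                          n_ligands_per_allele = 50L, decoy_fraction = 0.2,
                          seed = 99)
  a <- sample_ligandome(spec)
  b <- sample_ligandome(wider)
  for (al in c("A1", "A2")) {
    expect_identical(a$peptides$sequence[a$truth$label == al],
                     b$peptides$sequence[b$truth$label == al])
  }
})

test_that("modal generated lengths match the length-weight argmax", {
  spec1 <- ligandome_spec("A1", "I", n_ligands_per_allele = 1500L,
                          decoy_fraction = 0, seed = 23)
  lig1 <- sample_ligandome(spec1)
  tab1 <- table(nchar(lig1$peptides$sequence))
  expect_identical(names(which.max(tab1)), "9")

  spec2 <- ligandome_spec("D1", "II", n_ligands_per_allele = 1500L,
                          decoy_fraction = 0, seed = 23)
  lig2 <- sample_ligandome(spec2)
  tab2 <- table(nchar(lig2$peptides$sequence))
  expect_identical(names(which.max(tab2)), "15")
  expect_true(all(nchar(lig2$peptides$sequence) %in% 11:20))
  expect_true(all(nchar(lig1$peptides$sequence) %in% 8:14))
})

test_that("background proteome sampling is reproducible with plausible composition", {
  one <- sample_background_proteome(1, 50, seed = 3)
  expect_equal(nrow(one), 1L)
  expect_true(abs(nchar(one$sequence) - 50) < 30)  # Poisson around 50

  expect_identical(sample_background_proteome(10, 100, seed = 3),
                   sample_background_proteome(10, 100, seed = 3))

  big <- sample_background_proteome(150, 400, seed = 17)
  res <- strsplit(paste(big$sequence, collapse = ""), "")[[1]]
  n <- length(res)
  p <- background_frequencies()["A"]
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(res == "A") - p), 3 * se)
})

test_that("variant fixtures are valid and planted variants improve the motif score", {
  prot <- sample_background_proteome(40, 300, seed = 31)
  v <- make_variant_fixture(prot, 5, seed = 8)
  expect_equal(nrow(v), 5L)
  expect_true(all(v$ref_aa != v$alt_aa))
  plen <- nchar(prot$sequence)[match(v$protein_id, prot$protein_id)]
  expect_true(all(v$position >= 1L & v$position <= plen))

  spec <- ligandome_spec(c("A1", "A2"), "I", seed = 41)
  motifs <- make_allele_motifs(spec)
  vp <- make_variant_fixture(prot, 6, seed = 8, motifs = motifs,
                             planted_fraction = 0.5)
  planted <- vp[startsWith(vp$disease_label, "synthetic_planted"), ]
  expect_gte(nrow(planted), 3L)
  for (i in seq_len(nrow(planted))) {
    al <- sub("^synthetic_planted(_weak)?:", "", planted$disease_label[i])
    model <- model_from_motif(motifs[[al]], al)
    seqp <- prot$sequence[prot$protein_id == planted$protein_id[i]]
    win <- enumerate_variant_windows(seqp, planted[i, ], 9L)
    wt <- score_peptides(model, win$wt_peptide)
    mut <- score_peptides(model, win$mut_peptide)
    expect_true(any(mut > wt))
  }
})
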