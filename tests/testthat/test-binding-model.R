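test_that("map_to_core implements the identity / central-deletion / placeholder rules", {
  expect_identical(map_to_core("ABCDEFGHI"), "ABCDEFGHI")
  # 10-mer: delete 1 central residue, keeping ceiling(9/2) = 5 from the N side
  expect_identical(map_to_core("ABCDEFGHIJ"), "ABCDEGHIJ")
  expect_identical(map_to_core("ABCDEFGHIJKLMN"), "ABCDEKLMN")
  # 8-mer: neutral placeholder at the central core position
  expect_identical(map_to_core("ABCDEFGH"), "ABCD-EFGH")
  expect_error(map_to_core("ABCDEFG"), "cannot be mapped")
})

test_that("a single ligand with beta = 0 gives point-mass frequencies", {
  bg <- stats::setNames(rep(0.05, 20), aa_alphabet())
  m <- build_motif_model("AAAAAAAAA", "TOY", "I", beta = 0, background = bg)
  expect_equal(unname(m$log_odds[, "A"]), rep(log2(20), 9))
  expect_true(all(m$log_odds[, colnames(m$log_odds) != "A"] == -Inf))
  # closed form: matching 9-mer scores 9 * log2(20) bits
  expect_equal(score_peptide(m, "AAAAAAAAA"), 9 * log2(20))
})

test_that("pseudocount blending follows p = (n f + beta g) / (n + beta)", {
  # oracle: hand evaluation of the blending formula with the exported
  # BLOSUM62 conditionals, for one observation of A at every position
  g <- blosum62_conditionals()["A", ]
  expected_p <- (1 * (aa_alphabet() == "A") + 1 * g) / 2
  m <- build_motif_model("AAAAAAAAA", "TOY", "I", beta = 1)
  recovered_p <- 2^m$log_odds[3L, ] * m$background
  expect_equal(unname(recovered_p), unname(expected_p), tolerance = 1e-12)
})

test_that("trained probabilities stay normalised and anchors dominate", {
  f <- fix_class1()
  for (m in f$models) {
    recovered <- sweep(2^m$log_odds, 2L, m$background, "*")
    expect_equal(unname(rowSums(recovered)), rep(1, 9), tolerance = 1e-9)
  }
  # 100 ligands sharing anchor K at position 9 -> column argmax is K
  set.seed(71)
  lig <- vapply(1:100, function(i) {
    paste0(paste(sample(aa_alphabet(), 8, replace = TRUE), collapse = ""), "K")
  }, character(1))
  m <- build_motif_model(lig, "TOY", "I")
  expect_identical(names(which.max(m$log_odds[9L, ])), "K")
})

test_that("training errors on ligands shorter than the mappable window", {
  expect_error(build_motif_model(c("ABCDEFGHI", "MKVAILW"), "TOY", "I"),
               "MKVAILW")
  expect_error(build_motif_model("MKVAILWK", "TOY", "II"), "MKVAILWK")
})

test_that("motif recovery: anchors are recovered exactly at sharpness >= 0.7", {
  spec <- ligandome_spec("AL", "I", anchor_residues = list(AL = c("Y", "K")),
                         motif_sharpness = 0.7, n_ligands_per_allele = 250L,
                         decoy_fraction = 0, seed = 61)
  lig <- sample_ligandome(spec)
  m <- build_motif_model(lig$peptides$sequence, "AL", "I")
  expect_identical(names(which.max(m$log_odds[2L, ])), "Y")
  expect_identical(names(which.max(m$log_odds[9L, ])), "K")

  # class II: sliding-core refinement must find the register before the
  # anchors can line up
  f2 <- fix_class2()
  for (al in names(f2$models)) {
    prefs <- attr(f2$motifs[[al]], "anchor_residues")
    anchors <- attr(f2$motifs[[al]], "anchor_positions")
    got <- vapply(anchors, function(j) {
      names(which.max(f2$models[[al]]$log_odds[j, ]))
    }, character(1))
    expect_identical(got, prefs)
  }
})

test_that("class I scoring handles the 8-mer placeholder as exactly 0 bits", {
  f <- fix_class1()
  m <- f$models[[1L]]
  pep <- "FRSTWKLMY"
  core8 <- paste0(substr(pep, 1, 4), substr(pep, 6, 9))  # drop centre
  idx <- match(strsplit(pep, "")[[1]], aa_alphabet())
  full <- sum(m$log_odds[cbind(1:9, idx)])
  centre <- unname(m$log_odds[5L, idx[5L]])
  expect_equal(score_peptide(m, core8), full - centre)
})

test_that("class II scores are the maximum over sliding cores", {
  f2 <- fix_class2()
  m <- f2$models[[1L]]
  consensus <- paste(aa_alphabet()[apply(m$log_odds, 1L, which.max)],
                     collapse = "")
  embedded <- paste0("GPS", consensus, "AGV")
  expect_equal(score_peptide(m, embedded), score_peptide(m, consensus))
  # brute-force window oracle on an arbitrary 15-mer
  pep <- "WKLMYFRSTAQHNDE"
  manual <- max(vapply(1:7, function(o) {
    core <- substr(pep, o, o + 8L)
    idx <- match(strsplit(core, "")[[1]], aa_alphabet())
    sum(m$log_odds[cbind(1:9, idx)])
  }, numeric(1)))
  expect_equal(score_peptide(m, pep), manual)
})

test_that("a null model scores every peptide 0", {
  bg <- background_frequencies()
  null_model <- model_from_motif(matrix(rep(bg, each = 9), nrow = 9,
                                        dimnames = list(NULL, names(bg))),
                                 "NULL")
  expect_equal(score_peptides(null_model, c("ABCDEFGHI"[0], "SIINFEKLM",
                                            "AAAAAAAAA")),
               c(0, 0))
})

test_that("scoring rejects non-canonical residues", {
  f <- fix_class1()
  expect_error(score_peptide(f$models[[1L]], "SIINFEKLX"), "non-canonical")
})

test_that("calibration is deterministic with ascending arrays", {
  f <- fix_class1()
  m <- f$models[[1L]]
  c1 <- calibrate_ranks(m, fix_background(), lengths = 9L, M = 500L, seed = 4)
  c2 <- calibrate_ranks(m, fix_background(), lengths = 9L, M = 500L, seed = 4)
  expect_identical(c1, c2)
  expect_false(is.unsorted(c1$scores[["9"]]))
  tiny <- data.frame(protein_id = "P", sequence = "MKV")
  expect_error(calibrate_ranks(m, tiny, lengths = 9L, M = 10L), "no window")
})

test_that("percent_rank implements plus-one smoothed exceedance counting", {
  cal <- manual_calibration(seq_len(9999))
  expect_equal(percent_rank(cal, 1e6, 9L), 0.01)
  expect_equal(percent_rank(cal, -1e6, 9L), 100)
  expect_equal(percent_rank(cal, 5000, 9L), 50.01)  # median, ties counted >=
  expect_error(percent_rank(cal, 1, 12L), "length 12")

  # brute-force tie oracle on small arrays with duplicates
  set.seed(91)
  for (rep in 1:20) {
    bg <- sample(1:10, 25, replace = TRUE)
    cal <- manual_calibration(bg)
    s <- sample(0:11, 1)
    expect_equal(percent_rank(cal, s, 9L),
                 100 * (1 + sum(bg >= s)) / (length(bg) + 1))
  }
})

test_that("rank is monotone non-increasing in score", {
  f <- fix_class1()
  cal <- f$calibrations[[1L]]
  s <- sort(stats::runif(200, min(cal$scores[["9"]]) - 5,
                         max(cal$scores[["9"]]) + 5))
  r <- percent_rank(cal, s, 9L)
  expect_true(all(diff(r) <= 0))
})

test_that("self-calibration: background ranks are uniform on (0, 100]", {
  f <- fix_class1()
  m <- f$models[[1L]]
  cal <- calibrate_ranks(m, fix_background(), lengths = 9L, M = 10000L,
                         seed = 7)
  # fresh background windows from an independent stream
  fresh_cal <- calibrate_ranks(m, fix_background(), lengths = 9L, M = 10000L,
                               seed = 8)
  ranks <- percent_rank(cal, fresh_cal$scores[["9"]], 9L)
  ks <- suppressWarnings(stats::ks.test(ranks, "punif", 0, 100))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("consensus dominance holds under exhaustive 4-letter search", {
  letters4 <- c("A", "C", "D", "E")
  set.seed(81)
  lig <- vapply(1:200, function(i) {
    paste(sample(letters4, 9, replace = TRUE,
                 prob = c(0.55, 0.2, 0.15, 0.1)[sample(4)]), collapse = "")
  }, character(1))
  m <- build_motif_model(lig, "TOY", "I", beta = 5)
  consensus_res <- aa_alphabet()[apply(m$log_odds, 1L, which.max)]
  expect_true(all(consensus_res %in% letters4))
  consensus <- paste(consensus_res, collapse = "")

  grid <- do.call(expand.grid,
                  c(rep(list(letters4), 9), stringsAsFactors = FALSE))
  all_peps <- do.call(paste0, grid)
  scores <- score_peptides(m, all_peps)
  cmax <- score_peptide(m, consensus)
  expect_equal(max(scores), cmax)
  cal <- manual_calibration(scores[sample.int(length(scores), 5000)])
  expect_equal(percent_rank(cal, cmax, 9L), min(percent_rank(cal, scores, 9L)))
})

test_that("predictor JSON round-trips scores and ranks", {
  f <- fix_class1()
  path <- withr::local_tempfile(fileext = ".json")
  write_predictor_json(f$models, f$calibrations, path)
  back <- read_predictor_json(path)
  peps <- c("SIINFEKLM", "KVAELVHFLAQ", "WKLMYFRS")
  for (al in names(f$models)) {
    expect_equal(score_peptides(back$models[[al]], peps),
                 score_peptides(f$models[[al]], peps))
    expect_equal(percent_rank(back$calibrations[[al]], c(1.5, 20), 9L),
                 percent_rank(f$calibrations[[al]], c(1.5, 20), 9L))
  }
})
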