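test_that("binder classes follow the class-specific rank thresholds", {
  expect_identical(classify_binder(0.12, "II"), "strong")
  expect_identical(classify_binder(0.5, "I"), "weak")   # boundary exclusive
  expect_identical(classify_binder(5.0, "II"), "non")   # boundary exclusive
  expect_identical(classify_binder(c(0.49, 1.99, 2.0), "I"),
                   c("strong", "weak", "non"))
  expect_identical(classify_binder(c(0.99, 1.0, 4.99), "II"),
                   c("strong", "weak", "weak"))
})

test_that("assignment recovery: >= 90% of retained ligands go to their allele", {
  f <- fix_class1()
  asn <- fix_class1_assignments()
  truth <- truth_lookup(f$ligandome$truth)
  ret <- asn[asn$retained & truth[asn$peptide] != "decoy", ]
  expect_gt(nrow(ret), 500L)
  expect_gte(mean(ret$best_allele == truth[ret$peptide]), 0.90)
  # consistency invariants of the assignment frame
  rank_cols <- paste0("rank_", sort(names(f$models)))
  expect_equal(asn$best_rank,
               do.call(pmin, asn[rank_cols]))
  expect_identical(asn$binder_class, classify_binder(asn$best_rank, "I"))
})

test_that("decoy retention at the cutoff stays within 3 binomial SE of cutoff/100", {
  f <- fix_class1()
  asn <- fix_class1_assignments()
  truth <- truth_lookup(f$ligandome$truth)
  dec <- asn[truth[asn$peptide] == "decoy", ]
  p0 <- attr(asn, "rank_cutoff") / 100
  se <- sqrt(p0 * (1 - p0) / nrow(dec))
  expect_lt(abs(mean(dec$retained) - p0), 3 * se)
})

test_that("peptides outside the class window are skipped, not assigned", {
  f <- fix_class1()
  peps <- c("SIINFEKLM", "WKLMYFRSTAQHNDEA")  # 9-mer and 16-mer
  expect_message(asn <- deconvolute(peps, f$models, f$calibrations),
                 "1 peptide\\(s\\) outside")
  expect_equal(nrow(asn), 1L)
  expect_equal(attr(asn, "n_skipped"), 1L)
  expect_error(deconvolute(peps, list()), "empty allele set")
})

test_that("rank ties resolve to the lexicographically smallest allele", {
  f <- fix_class1()
  const_rank <- function(peptides, allele) rep(1.0, length(peptides))
  asn <- deconvolute("SIINFEKLM", f$models, rank_fun = const_rank)
  expect_identical(asn$best_allele, min(names(f$models)))
  expect_true(asn$retained)
})

test_that("length_distribution counts what it should", {
  asn <- data.frame(peptide = c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD",
                                "EEEEEEEEEE"),
                    length = c(9L, 9L, 9L, 10L),
                    retained = c(TRUE, TRUE, TRUE, TRUE))
  expect_identical(length_distribution(asn), c(`9` = 3L, `10` = 1L))
  asn$retained[4L] <- FALSE
  expect_identical(length_distribution(asn), c(`9` = 3L))
  expect_identical(length_distribution(asn, retained_only = FALSE),
                   c(`9` = 3L, `10` = 1L))
  expect_length(length_distribution(asn[0, ]), 0L)
  # histogram mass equals retained count on the big fixture
  big <- fix_class1_assignments()
  expect_equal(sum(length_distribution(big)), sum(big$retained))
})

test_that("top_epitopes_per_allele sorts, truncates and breaks ties lexicographically", {
  asn <- data.frame(peptide = c("CCC", "AAA", "BBB", "DDD", "EEE"),
                    best_allele = c("X", "X", "X", "Y", "Y"),
                    best_rank = c(0.3, 0.1, 0.2, 0.5, 0.5),
                    binder_class = "strong",
                    retained = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  top <- top_epitopes_per_allele(asn, n = 2L)
  expect_identical(top$peptide[top$allele == "X"], c("AAA", "BBB"))
  expect_identical(top$peptide[top$allele == "Y"], c("DDD", "EEE"))  # tie
  # truncation floor: fewer retained than n
  top3 <- top_epitopes_per_allele(asn[asn$best_allele == "Y", ], n = 3L)
  expect_equal(nrow(top3), 2L)
})

test_that("overlap_summary reproduces printed shares and exact partitions", {
  venn <- overlap_summary_counts(c(1749, 346, 2584))
  expect_equal(venn$shared_pct, 37)
  expect_equal(venn$unique_a_pct, 7)
  expect_equal(venn$unique_b_pct, 55)

  same <- overlap_summary(letters[1:5], letters[1:5])
  expect_equal(unlist(same[c("shared", "unique_a", "unique_b")]),
               c(shared = 5, unique_a = 0, unique_b = 0))
  expect_equal(same$shared_pct, 100)

  dis <- overlap_summary("z", c("p", "q", "r"))
  expect_equal(unlist(dis[c("shared", "unique_a", "unique_b",
                            "unique_a_pct", "unique_b_pct")]),
               c(shared = 0, unique_a = 1, unique_b = 3,
                 unique_a_pct = 25, unique_b_pct = 75))

  set.seed(55)
  for (i in 1:10) {
    a <- sample(letters, sample(0:20, 1))
    b <- sample(letters, sample(0:20, 1))
    o <- overlap_summary(a, b)
    expect_equal(o$shared + o$unique_a + o$unique_b,
                 length(union(a, b)))
  }
})

test_that("filter_epitope_table is inclusive at the boundary and monotone", {
  t1 <- load_table1_fixture()
  at7 <- filter_epitope_table(t1, 7)
  at2 <- filter_epitope_table(t1, 2)
  expect_true(all(at2$rows$peptide %in% at7$rows$peptide))
  # boundary inclusive: a row printed exactly at the cutoff is retained
  at089 <- filter_epitope_table(t1, 0.89)
  expect_true("TPSLPTPPTR" %in% at089$rows$peptide)
  # monotone over a cutoff ladder
  sizes <- vapply(c(0.5, 1, 2, 5, 7), function(ct)
    filter_epitope_table(t1, ct)$n_retained, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  empty <- filter_epitope_table(t1[0, ], 7)
  expect_equal(c(empty$n_retained, empty$n_genes), c(0L, 0L))
})
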