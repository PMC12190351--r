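---
title: "Methods: motif scoring, rank calibration and the synthetic ligandome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif scoring, rank calibration and the synthetic ligandome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcdeconv)
```

## Scope and model choice

`mhcdeconv` reproduces the *rank-threshold semantics* of modern eluted-ligand
predictors — percentile ranks per allele, class-specific retention cutoffs,
strong/weak binder classes — with a transparent, trainable scoring model
rather than a pretrained artificial neural network. Reusing a neural
predictor's trained weights is deliberately out of scope: the package's
contribution is a self-contained pipeline whose every number can be traced
to counted frequencies and sampled backgrounds. A predictor adapter (the
`rank_fun` argument of `deconvolute()`) lets an external executable's ranks
be substituted without touching the rest of the pipeline; nothing in the
test suite requires one.

Numeric rank agreement with any external tool is therefore *not* claimed;
published epitope tables are used for threshold and count checks only.

## The binding model

For each allele we estimate a position-specific scoring matrix over a
9-residue binding core. With $n$ aligned training cores, observed residue
frequencies $f_j$ at core position $j$, and BLOSUM62-conditional pseudocount
frequencies $g_j(b) = \sum_a f_j(a)\, g(b \mid a)$:

$$p_j = \frac{n f_j + \beta g_j}{n + \beta}, \qquad
  \mathrm{lo}_j(b) = \log_2 \frac{p_j(b)}{q(b)}$$

where $q$ is the background frequency vector. A peptide's score is the sum
of per-position log-odds, in bits.

* **β (pseudocount weight), default 50.** Interpolates toward the BLOSUM62
  conditionals for small ligand sets; with hundreds of ligands the observed
  frequencies dominate. `beta = 0` disables smoothing (used in tests to get
  exact point-mass columns).
* **BLOSUM62 conditionals.** Reconstructed from the Biostrings integer
  score matrix via $q_{ab} \propto p_a p_b\, 2^{s_{ab}/2}$ (half-bit scale)
  with the package background as marginals, then row-normalised. This is an
  approximate inversion of the published log-odds rounding; it is
  deterministic and documented, and the pseudocount target it yields is
  substitution-aware, which is all the smoothing needs.
* **Background frequencies.** A fixed built-in table approximating
  vertebrate proteome composition (near-uniform with mild realism). A
  built-in table removes any dependence on external proteome downloads and
  makes every log-odds reproducible from the package alone.

### Core mapping (class I)

Class I grooves are closed: both termini anchor. Peptides of 8–14 residues
map onto the 9-position core by keeping `ceiling(9/2) = 5` residues from
the N side and the C-terminal remainder, deleting the central bulge of
longer peptides; 8-mers insert a neutral placeholder at the central
position, scored as **exactly 0 bits** (neutral under the log-odds null —
no evidence for or against). This makes every class I length scorable
against one matrix while leaving the anchor positions intact.

### Sliding-core alignment (class II)

Class II grooves are open: an 11–20-mer engages a 9-residue core at an
unknown register. Scoring takes the maximum over all contiguous 9-mer
windows. Training must discover the register: cores initialise at the
N-terminal 9-mer, then the matrix is rebuilt and every ligand re-aligned to
its best-scoring core, iterating to a fixed point (cap 20 iterations, ties
broken toward the smaller offset — a deterministic convention, not a
biological claim). This standard fixed-point refinement converges in a
handful of iterations on motif-bearing data; the test suite verifies that
all anchors of the generating motifs are recovered exactly.

## Percentile-rank calibration

A raw bit score is not comparable across alleles; the pipeline's currency
is the *eluted-ligand percentile rank*: the percentage of background
peptides scoring at least as high,

$$\mathrm{rank} = 100\,\frac{1 + \#\{\text{background} \ge s\}}{M + 1}.$$

The plus-one smoothing keeps ranks strictly inside $(0, 100]$ — a peptide
above every background window gets $100/(M+1)$, never an unfalsifiable 0.
Ranks of fresh background peptides are uniform on $(0, 100]$ by
construction (verified by a Kolmogorov–Smirnov check at $M = 10{,}000$),
which is what makes "retained at cutoff $c$" mean "false-positive rate
$\approx c/100$" for motif-free peptides.

* **Per-length calibration (class I).** A 9-mer is ranked against
  background 9-mers, a 12-mer against 12-mers: length-dependent score
  offsets (from the deletion mapping) cancel within each length.
* **Single-length calibration (class II).** All queries rank against
  15-mer background windows — the modal observed class II length. Because
  class II scores are maxima over sliding windows, the window count (hence
  the score distribution) varies with length; pinning the background length
  keeps ranks comparable across the class II range at the cost of a mild
  length bias, which the retention cutoff of 5% absorbs.
* **M, default 10,000 in production.** Rank resolution is $100/(M+1)$;
  the strong-binder bound of 0.5% needs $M \gtrsim 1000$ to be meaningful.
  Tests use smaller $M$ (1000–5000) purely for speed, never below the
  resolution needed by the threshold being tested.

## Deconvolution

Peptides are deduplicated by sequence (assignment is a property of the
sequence; per-sample counts can be re-expanded against `sample_id`
afterwards), peptides outside the class length window (8–14 / 11–20) are
skipped with a reported count, and each remaining peptide is assigned to
its minimum-rank allele — ties toward the lexicographically smallest allele
name, a deterministic convention. Retention uses strict `<` against the
cutoff (2% class I, 5% class II), matching the "below x%" phrasing of
rank-threshold practice; binder classes use the same strictness (strong
below 0.5% / 1%). One deliberate asymmetry: `filter_epitope_table()`, which
filters *printed* report tables rather than raw ranks, compares with `<=`,
so a row published exactly at the boundary is retained rather than dropped
by a rounding artefact.

## The variant scan

For a protein point variant (1-based position, reference residue checked
against the FASTA), `enumerate_variant_windows()` emits every fully
contained window of every requested length that covers the position, paired
wildtype/mutant. Defaults: class I lengths 8–14 (the observed deconvoluted
window); class II length 15 (the modal class II length; 11–20 available via
the `lengths` argument, at ~10× the window count). Every (window, allele)
pair is ranked for both sequences and a candidate is kept iff

$$\text{mut\_rank} \le \text{wt\_rank} \quad\wedge\quad
  \text{mut\_rank} < \text{strong bound}.$$

The comparison is non-strict by default — "binds at least as strongly" —
with `strict = TRUE` available; the strong-binder gate applies to the
mutant only (the wildtype rank is reported, not gated). All candidates are
returned with their flags so the filter is auditable.
`summarize_scan()` deduplicates by (allele, mutant peptide), keeping the
best-scoring window register; overlapping windows yielding the same mutant
peptide are one epitope, not several. That collapsing rule is a package
choice (reported epitope counts elsewhere may or may not collapse
registers).

## The synthetic ligandome: what it emulates, and what a green test means

The generator is the package's stand-in for deposited raw immunopeptidome
data. Its defaults state a fixed world:

* class I lengths 8–14 with mode 9, class II lengths 11–20 with mode 15
  (default `length_weights`), matching eluted-ligand length distributions;
* per-allele anchor motifs: 2 anchors (core positions 2 and 9) for class I,
  3 (positions 1, 4, 9) for class II, with `motif_sharpness` (default 0.8)
  probability mass on one preferred residue per anchor and the remainder
  spread over the other 19 in background proportion; non-anchor columns are
  a mild Dirichlet perturbation of background (concentration 500).
  Automatically drawn anchor residues are restricted to background
  frequency < 5% — real groove pockets prefer distinctive side chains, and
  an anchor on leucine would be nearly uninformative;
* decoys drawn i.i.d. from background with uniform length over the class
  window; `decoy_fraction` is the decoy share of all emitted peptides;
* class II ligands embed the 9-mer core at a uniform register with
  background flanks; class I ligands invert the scoring core-mapping, so
  core-mapping a ligand recovers its motif draw;
* planted variants for the scan: the generator searches for windows whose
  other anchors already match and substitutes the preferred residue at the
  one mismatched anchor, guaranteeing a mutant that outscores wildtype and
  (anchors being background-rare) clears the strong bound;
* one master seed expands into named child streams (one per allele, one for
  decoys), so adding an allele never perturbs another allele's sample, and
  every output is bitwise reproducible.

The generator does **not** emulate MS acquisition: no spectra, no
chromatography, no co-eluting contaminants, no intensity missingness, no
source-protein correlation between ligands, no stimulation effect sizes. A
green synthetic test therefore establishes that the *pipeline machinery* —
training, calibration, assignment, thresholds, enumeration — behaves as
specified under the stated statistical structure; it does not establish
predictive accuracy on real eluted ligands, which depends on motif quality
no desk-scale test can certify.

## Numerical conventions and degenerate inputs

* Rank ties in assignment → lexicographically smallest allele name; rank
  ties in top-epitope lists → lexicographic peptide order.
* Class II core-refinement ties → smallest offset.
* `beta = 0` with unseen residues yields $-\infty$ log-odds; scores may be
  $-\infty$, ranks saturate at 100. Supported, intended for controlled
  tests.
* Peptides containing non-canonical letters (B/J/O/U/X/Z, digits) are
  rejected at scoring time and dropped (with a count) or refused at
  ingestion, by flag: the binding model has no column for them.
* Empty allele sets, reference-residue mismatches, out-of-bounds variant
  positions, and unparseable rank labels are hard errors naming the
  offending record.
* Percentages in overlap summaries round half-up to whole percent, so the
  three printed shares need not sum to 100.

## Configuration and pipeline

`pipeline_config()` validates the invariants up front (cutoffs and bounds
in (0, 100), strong bound strictly below the retention cutoff, integer
seed) and serializes to JSON — chosen over YAML because the deployment
environment guarantees a JSON reader but no YAML parser; the round-trip
contract is unchanged. `run_pipeline()` executes
simulate → train → calibrate → deconv → scan with per-stage child seeds,
logs every applied threshold and dropped-record count, writes a
`report.json` with per-stage record counts, and aborts naming the failing
stage. The simulate stage emits a decoy-free *training* ligandome and an
independent decoy-bearing *detection* ligandome sharing the same
ground-truth motifs, so trained models are never evaluated on their own
training peptides.

## Known limitations

* The PSSM assumes position independence within the core; real grooves
  show pairwise pocket coupling that only richer models capture.
* Class II calibration against 15-mers only introduces a small
  length-dependent rank bias (see above).
* The scan does not check mutant peptides against the rest of the proteome
  (a mutant epitope identical to some other self-peptide would still be
  reported), and immunogenicity is out of scope entirely.
* Acceptance-scale checks of the length-mode behaviour in the test suite
  run at reduced size (700 ligands/allele, M = 4000) to respect the test
  budget; the acceptance script runs the full stated setup (2000/allele,
  M = 10,000).
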