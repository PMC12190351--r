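#' Canonical amino-acid alphabet
#'
#' The twenty canonical residues in the conventional one-letter ordering used
#' throughout the package. All scoring matrices index their columns in this
#' order; peptides containing any other letter (B, J, O, U, X, Z, ...) are
#' rejected by the readers or dropped on request.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Built-in background amino-acid frequencies
#'
#' A fixed, package-internal frequency table approximating the residue
#' composition of a vertebrate proteome (near-uniform with mild realism:
#' Leu/Ala/Ser common, Trp/Cys rare). Used as the default null model for
#' log-odds matrices, for sampling synthetic background proteomes and decoy
#' peptides, and for spreading non-anchor probability mass in simulated
#' motifs. Keeping the table built in removes any dependency on external
#' proteome downloads.
#'
#' @return Named numeric vector over [aa_alphabet()] summing to exactly 1.
#' @export
background_frequencies <- function() {
  f <- c(A = 0.0777, C = 0.0157, D = 0.0530, E = 0.0656, F = 0.0405,
         G = 0.0691, H = 0.0227, I = 0.0591, K = 0.0580, L = 0.0960,
         M = 0.0238, N = 0.0427, P = 0.0469, Q = 0.0393, R = 0.0526,
         S = 0.0722, T = 0.0584, V = 0.0667, W = 0.0113, Y = 0.0321)
  f / sum(f)
}

#' BLOSUM62 conditional substitution frequencies
#'
#' Row-stochastic matrix \eqn{g(b \mid a)}: the probability that a residue
#' aligned to `a` in a BLOSUM62-scored alignment is `b`. Reconstructed from
#' the published integer BLOSUM62 log-odds scores \eqn{s_{ab}} (half-bit
#' units) via \eqn{q_{ab} \propto p_a p_b 2^{s_{ab}/2}} with the built-in
#' background as marginals, then row-normalised. Used as the pseudocount
#' source when estimating position-specific residue frequencies from small
#' ligand sets, so sparse columns are smoothed toward residues that are
#' substitutable for the observed ones rather than toward uniform noise.
#'
#' @return 20 x 20 matrix, rows and columns in [aa_alphabet()] order; every
#'   row sums to 1.
#' @export
blosum62_conditionals <- function() {
  .mhc_cache_get("blosum62_cond", {
    aa <- aa_alphabet()
    bl <- get_blosum62_scores()[aa, aa]
    p <- background_frequencies()
    q <- outer(p, p) * 2^(bl / 2)
    g <- q / rowSums(q)
    dimnames(g) <- list(aa, aa)
    g
  })
}

get_blosum62_scores <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# tiny per-session memo cache; everything stored is deterministic
.mhc_cache <- new.env(parent = emptyenv())
.mhc_cache_get <- function(key, expr) {
  if (!exists(key, envir = .mhc_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .mhc_cache)
  }
  get(key, envir = .mhc_cache, inherits = FALSE)
}

#' Split peptides into a residue index matrix
#'
#' @param peptides character vector of equal-length peptide sequences.
#' @param allow_gap if `TRUE`, the placeholder character `"-"` is mapped to
#'   `NA` (scored as zero log-odds) instead of raising an error.
#' @return integer matrix, one row per peptide, entries indexing
#'   [aa_alphabet()].
#' @keywords internal
peptide_index_matrix <- function(peptides, allow_gap = FALSE) {
  if (length(peptides) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = 0L))
  }
  n <- unique(nchar(peptides))
  if (length(n) != 1L) {
    stop("peptides must all have the same length", call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(peptides), ncol = n, byrow = TRUE)
  idx <- match(chars, aa_alphabet())
  dim(idx) <- dim(chars)
  bad <- is.na(idx) & chars != "-"
  if (any(bad)) {
    offending <- unique(chars[bad])
    stop("non-canonical residue(s): ", paste(offending, collapse = ", "),
         call. = FALSE)
  }
  if (!allow_gap && any(chars == "-")) {
    stop("placeholder '-' not allowed here", call. = FALSE)
  }
  idx
}

#' Validate peptide sequences against the canonical alphabet
#'
#' @param x character vector.
#' @return logical vector: `TRUE` where `x` is a non-empty string over the
#'   twenty canonical residues.
#' @export
is_valid_peptide <- function(x) {
  nzchar(x) & !is.na(x) &
    grepl(paste0("^[", paste(aa_alphabet(), collapse = ""), "]+$"), x)
}

#' Deterministic child seed derivation
#'
#' Expands one integer seed into independent named sub-seeds (one per allele,
#' one per pipeline stage, ...) so that adding a consumer never perturbs the
#' random stream of another. Implements a small multiplicative string hash
#' folded into the seed, reduced modulo 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param label character label of the consumer.
#' @return integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(label) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

round_half_up <- function(x) floor(x + 0.5)
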