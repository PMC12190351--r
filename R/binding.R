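#' Map a class I peptide onto a fixed-length scoring core
#'
#' Class I grooves bind peptides of 8-14 residues against a 9-position
#' scoring matrix. The mapping keeps both termini (the anchor-bearing ends)
#' and treats the centre as the flexible bulge:
#' * length equal to the core: identity;
#' * length above the core: the excess central residues are deleted, keeping
#'   `ceiling(core_length / 2)` residues from the N-terminal side;
#' * length one below the core: a neutral placeholder `"-"` (scored as
#'   exactly 0 log-odds) is inserted at the central position.
#'
#' @param peptide single peptide string.
#' @param core_length core width (default 9).
#' @return string of length `core_length`, possibly containing `"-"`.
#' @export
map_to_core <- function(peptide, core_length = 9L) {
  L <- nchar(peptide)
  if (L == core_length) return(peptide)
  keep_n <- as.integer(ceiling(core_length / 2))
  if (L > core_length) {
    paste0(substr(peptide, 1L, keep_n),
           substr(peptide, L - (core_length - keep_n) + 1L, L))
  } else if (L == core_length - 1L) {
    paste0(substr(peptide, 1L, keep_n - 1L), "-",
           substr(peptide, keep_n, L))
  } else {
    stop("peptide '", peptide, "' (length ", L,
         ") cannot be mapped to a ", core_length, "-position core",
         call. = FALSE)
  }
}

#' Train a per-allele position-specific scoring matrix
#'
#' Estimates, for every core position, the residue frequencies of the
#' training ligands, blends them with BLOSUM62-conditional pseudocount
#' frequencies, and converts to log2 odds against the background:
#' \deqn{p = (n f + \beta g) / (n + \beta), \quad
#'       \mathrm{log\_odds} = \log_2(p / \mathrm{background})}
#' where `f` are observed frequencies, `n` the number of (real, non
#' placeholder) observations at the position, and
#' `g(b) = sum_a f(a) g(b | a)` mixes the BLOSUM62 conditionals over the
#' observed column.
#'
#' Class I ligands are first mapped onto the core with [map_to_core()]
#' (placeholders contribute no counts). Class II ligands are core-aligned by
#' fixed-point refinement: cores start at the N-terminal 9-mer, then the
#' matrix is rebuilt and every ligand re-aligned to its best-scoring
#' contiguous core (ties toward the smaller offset) until the assignment is
#' stable or `max_iter` passes.
#'
#' @param ligands character vector of training peptides.
#' @param allele allele name stored in the model.
#' @param hla_class `"I"` or `"II"`.
#' @param core_length core width (default 9).
#' @param beta pseudocount weight (default 50; 0 disables smoothing).
#' @param background background residue frequencies (20-vector summing to 1).
#' @param max_iter class II refinement cap.
#' @return object of class `"AlleleMotifModel"`: allele metadata, the
#'   `core_length` x 20 `log_odds` matrix, `beta`, `background`, and
#'   `n_training_ligands`.
#' @export
build_motif_model <- function(ligands, allele, hla_class = "I",
                              core_length = 9L, beta = 50,
                              background = background_frequencies(),
                              max_iter = 20L) {
  hla_class <- match.arg(hla_class, c("I", "II"))
  stopifnot(length(ligands) >= 1L, core_length >= 1L, beta >= 0)
  if (abs(sum(background) - 1) > 1e-8) {
    stop("background frequencies must sum to 1", call. = FALSE)
  }
  short <- nchar(ligands) < (if (hla_class == "I") core_length - 1L else core_length)
  if (any(short)) {
    stop("ligand '", ligands[which(short)[1L]], "' is shorter than the ",
         core_length, "-residue core", call. = FALSE)
  }
  if (hla_class == "I") {
    cores <- vapply(ligands, map_to_core, character(1),
                    core_length = core_length, USE.NAMES = FALSE)
    lo <- pssm_from_cores(cores, core_length, beta, background)
  } else {
    lo <- refine_class2_cores(ligands, core_length, beta, background, max_iter)
  }
  structure(list(allele = allele, hla_class = hla_class,
                 core_length = as.integer(core_length),
                 log_odds = lo, beta = beta, background = background,
                 n_training_ligands = length(ligands)),
            class = "AlleleMotifModel")
}

# frequency -> blended probability -> log2-odds for a set of aligned cores
pssm_from_cores <- function(cores, core_length, beta, background) {
  idx <- peptide_index_matrix(cores, allow_gap = TRUE)
  G <- blosum62_conditionals()
  lo <- matrix(NA_real_, nrow = core_length, ncol = 20L,
               dimnames = list(NULL, aa_alphabet()))
  for (j in seq_len(core_length)) {
    obs <- idx[, j]
    obs <- obs[!is.na(obs)]
    n <- length(obs)
    if (n == 0L) {
      p <- background  # column of pure placeholders: fall back to the null
    } else {
      f <- tabulate(obs, nbins = 20L) / n
      g <- as.vector(f %*% G)
      p <- (n * f + beta * g) / (n + beta)
    }
    lo[j, ] <- log2(p / background)
  }
  lo
}

refine_class2_cores <- function(ligands, core_length, beta, background,
                                max_iter) {
  offsets <- rep(0L, length(ligands))  # 0-based core start
  lo <- NULL
  for (iter in seq_len(max_iter)) {
    cores <- substr(ligands, offsets + 1L, offsets + core_length)
    lo <- pssm_from_cores(cores, core_length, beta, background)
    new_off <- best_core_offsets(ligands, lo, core_length)
    if (identical(new_off, offsets)) break
    offsets <- new_off
  }
  # matrix consistent with the final alignment
  pssm_from_cores(substr(ligands, offsets + 1L, offsets + core_length),
                  core_length, beta, background)
}

# per ligand, 0-based offset of the best-scoring core window (ties -> smaller)
best_core_offsets <- function(ligands, log_odds, core_length) {
  out <- integer(length(ligands))
  lens <- nchar(ligands)
  for (L in unique(lens)) {
    sel <- which(lens == L)
    n_win <- L - core_length + 1L
    sc <- matrix(-Inf, nrow = length(sel), ncol = n_win)
    for (o in seq_len(n_win)) {
      sc[, o] <- score_aligned_cores(substr(ligands[sel], o, o + core_length - 1L),
                                     log_odds)
    }
    out[sel] <- max.col(sc, ties.method = "first") - 1L
  }
  out
}

# sum of per-position log-odds over equal-length core strings ("-" scores 0)
score_aligned_cores <- function(cores, log_odds) {
  if (length(cores) == 0L) return(numeric(0))
  idx <- peptide_index_matrix(cores, allow_gap = TRUE)
  core_length <- ncol(idx)
  pos <- matrix(rep(seq_len(core_length), each = nrow(idx)), nrow = nrow(idx))
  val <- log_odds[pos + (idx - 1L) * core_length]
  val[is.na(idx)] <- 0
  rowSums(matrix(val, nrow = nrow(idx)))
}

#' @export
print.AlleleMotifModel <- function(x, ...) {
  cons <- aa_alphabet()[apply(x$log_odds, 1L, which.max)]
  cat("PSSM binding model for ", x$allele, " (class ", x$hla_class, ")\n",
      "  core length ", x$core_length, ", beta ", x$beta,
      ", trained on ", x$n_training_ligands, " ligand(s)\n",
      "  consensus core: ", paste(cons, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Score peptides against a binding model
#'
#' Class I peptides are mapped to the core with [map_to_core()] and scored as
#' the sum of per-position log2 odds (placeholders contribute 0 bits). Class
#' II peptides are scored as the maximum over every contiguous core-length
#' window, the sliding-core convention for the open class II groove.
#'
#' @param model an [build_motif_model()] object.
#' @param peptides character vector.
#' @return numeric vector of scores in bits.
#' @export
score_peptides <- function(model, peptides) {
  stopifnot(inherits(model, "AlleleMotifModel"))
  if (length(peptides) == 0L) return(numeric(0))
  lens <- nchar(peptides)
  out <- numeric(length(peptides))
  if (model$hla_class == "I") {
    cores <- vapply(peptides, map_to_core, character(1),
                    core_length = model$core_length, USE.NAMES = FALSE)
    for (L in unique(nchar(cores))) {
      sel <- nchar(cores) == L
      out[sel] <- score_aligned_cores(cores[sel], model$log_odds)
    }
  } else {
    if (any(lens < model$core_length)) {
      stop("peptide shorter than the class II core", call. = FALSE)
    }
    for (L in unique(lens)) {
      sel <- which(lens == L)
      n_win <- L - model$core_length + 1L
      sc <- matrix(-Inf, nrow = length(sel), ncol = n_win)
      for (o in seq_len(n_win)) {
        sc[, o] <- score_aligned_cores(
          substr(peptides[sel], o, o + model$core_length - 1L), model$log_odds)
      }
      out[sel] <- apply(sc, 1L, max)
    }
  }
  out
}

#' @rdname score_peptides
#' @param peptide single peptide string.
#' @export
score_peptide <- function(model, peptide) {
  stopifnot(length(peptide) == 1L)
  score_peptides(model, peptide)
}
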