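#' Calibrate model scores to percentile ranks against a background proteome
#'
#' Samples, for each requested peptide length, `M` windows uniformly from the
#' background proteome (proteins weighted by the number of windows they can
#' host, starts uniform within a protein), scores them with the model and
#' stores the sorted score arrays. A query score is then expressed as the
#' percentage of background peptides scoring at least as high — the
#' eluted-ligand percentile-rank semantics in which smaller means stronger
#' predicted presentation.
#'
#' Class I calibration is per length (a query is ranked against background
#' windows of its own length). Class II calibration uses 15-mer background
#' windows for all query lengths, the modal observed class II length, so
#' ranks stay comparable across the open-groove length range; `lengths`
#' therefore defaults to 15 for class II and to 8-14 for class I.
#'
#' @param model an [build_motif_model()] object.
#' @param proteome data.frame with `protein_id` and `sequence` columns.
#' @param lengths integer vector of background window lengths.
#' @param M background sample size per length (production floor 1000; smaller
#'   values are allowed but flagged for tests and toy examples).
#' @param seed integer seed; sampling is bitwise reproducible.
#' @return object of class `"RankCalibration"`: sorted score array and `M`
#'   per length, allele metadata, `seed`, `source`.
#' @export
calibrate_ranks <- function(model, proteome, lengths = NULL, M = 10000L,
                            seed = 1L) {
  stopifnot(inherits(model, "AlleleMotifModel"), nrow(proteome) >= 1L,
            M >= 1L)
  if (is.null(lengths)) {
    lengths <- if (model$hla_class == "I") 8:14 else 15L
  }
  lengths <- sort(unique(as.integer(lengths)))
  set.seed(derive_seed(seed, paste0("calibrate/", model$allele)))
  plen <- nchar(proteome$sequence)
  scores <- vector("list", length(lengths))
  names(scores) <- as.character(lengths)
  for (L in lengths) {
    n_win <- pmax(0L, plen - L + 1L)
    if (sum(n_win) < 1L) {
      stop("background proteome has no window of length ", L, call. = FALSE)
    }
    pi <- sample.int(nrow(proteome), M, replace = TRUE, prob = n_win)
    start <- 1L + floor(stats::runif(M) * n_win[pi])
    peps <- substr(proteome$sequence[pi], start, start + L - 1L)
    scores[[as.character(L)]] <- sort(score_peptides(model, peps))
  }
  structure(list(allele = model$allele, hla_class = model$hla_class,
                 lengths = lengths, scores = scores,
                 M = vapply(scores, length, integer(1)),
                 source = paste0(nrow(proteome), "-protein background"),
                 seed = as.integer(seed)),
            class = "RankCalibration")
}

#' @export
print.RankCalibration <- function(x, ...) {
  cat("Rank calibration for ", x$allele, " (class ", x$hla_class, "): ",
      "lengths {", paste(x$lengths, collapse = ", "), "}, M = ",
      x$M[[1L]], ", ", x$source, "\n", sep = "")
  invisible(x)
}

#' Convert a score to an eluted-ligand-style percentile rank
#'
#' \deqn{\mathrm{rank} = 100 (1 + \#\{\mathrm{background} \ge s\}) / (M + 1)}
#' The plus-one smoothing keeps ranks strictly inside (0, 100]: a score above
#' every background score gets rank `100 / (M + 1)`, never 0. The rank is
#' non-increasing in the score, strictly decreasing across the background's
#' score range.
#'
#' @param calibration a [calibrate_ranks()] object.
#' @param score numeric vector of scores (bits).
#' @param length peptide length(s), recycled against `score`; class II
#'   queries are ranked against the single stored background length
#'   regardless of their own.
#' @return numeric vector of ranks in (0, 100] on the percent scale.
#' @export
percent_rank <- function(calibration, score, length) {
  stopifnot(inherits(calibration, "RankCalibration"))
  if (calibration$hla_class == "II") {
    length <- rep(calibration$lengths[1L], base::length(score))
  }
  n <- max(base::length(score), base::length(length))
  score <- rep_len(score, n)
  length <- rep_len(as.integer(length), n)
  out <- numeric(n)
  for (L in unique(length)) {
    key <- as.character(L)
    if (!key %in% names(calibration$scores)) {
      stop("no calibration for peptide length ", L, call. = FALSE)
    }
    bg <- calibration$scores[[key]]
    M <- base::length(bg)
    sel <- length == L
    n_lt <- findInterval(score[sel], bg, left.open = TRUE)
    out[sel] <- 100 * (1 + (M - n_lt)) / (M + 1)
  }
  out
}

# JSON (de)serialization ----------------------------------------------------

#' Serialize models and calibrations to JSON
#'
#' Writes a documented JSON bundle: per allele, the log-odds matrix
#' (row-major, one array per core position), pseudocount weight, background
#' frequencies and training size, plus the sorted calibration arrays with
#' their `M` and seed. [read_predictor_json()] restores objects that score
#' and rank identically.
#'
#' @param models named list of [build_motif_model()] objects.
#' @param calibrations named list of [calibrate_ranks()] objects (same
#'   names), or `NULL` to serialize models only.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictor_json <- function(models, calibrations = NULL, path) {
  enc_model <- function(m) {
    list(allele = m$allele, hla_class = m$hla_class,
         core_length = m$core_length,
         log_odds = apply(m$log_odds, 1L, function(r) unname(r),
                          simplify = FALSE),
         beta = m$beta,
         background = as.list(m$background),
         n_training_ligands = m$n_training_ligands)
  }
  enc_cal <- function(cl) {
    list(allele = cl$allele, hla_class = cl$hla_class,
         lengths = cl$lengths, scores = cl$scores,
         M = as.list(cl$M), source = cl$source, seed = cl$seed)
  }
  bundle <- list(format = "mhcdeconv-predictor", version = 1L,
                 models = lapply(models, enc_model),
                 calibrations = if (!is.null(calibrations))
                   lapply(calibrations, enc_cal))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Restore models and calibrations from JSON
#'
#' @param path file written by [write_predictor_json()].
#' @return list with named lists `models` and `calibrations` (the latter
#'   `NULL` when absent from the file).
#' @export
read_predictor_json <- function(path) {
  bundle <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(bundle$format, "mhcdeconv-predictor")) {
    stop("'", path, "' is not a predictor bundle", call. = FALSE)
  }
  dec_model <- function(e) {
    lo <- do.call(rbind, lapply(e$log_odds, function(r)
      vapply(r, as.numeric, numeric(1))))
    colnames(lo) <- aa_alphabet()
    bgl <- vapply(e$background, as.numeric, numeric(1))
    structure(list(allele = e$allele, hla_class = e$hla_class,
                   core_length = as.integer(e$core_length), log_odds = lo,
                   beta = as.numeric(e$beta),
                   background = stats::setNames(bgl, names(e$background)),
                   n_training_ligands = as.integer(e$n_training_ligands)),
              class = "AlleleMotifModel")
  }
  dec_cal <- function(e) {
    sc <- lapply(e$scores, function(v) vapply(v, as.numeric, numeric(1)))
    structure(list(allele = e$allele, hla_class = e$hla_class,
                   lengths = vapply(e$lengths, as.integer, integer(1)),
                   scores = sc,
                   M = vapply(sc, length, integer(1)),
                   source = e$source, seed = as.integer(e$seed)),
              class = "RankCalibration")
  }
  list(models = lapply(bundle$models, dec_model),
       calibrations = if (!is.null(bundle$calibrations))
         lapply(bundle$calibrations, dec_cal))
}
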