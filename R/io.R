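#' Read a protein FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that enforces the
#' package's conventions: sequences are uppercased, a single trailing `*`
#' stop character is stripped, record order is preserved, and the identifier
#' is the first whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @return data.frame with columns `protein_id`, `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) {
                    stop("malformed FASTA '", path, "': ", conditionMessage(e),
                         call. = FALSE)
                  })
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(ids))) {
    stop("malformed FASTA header at record ", which(!nzchar(ids))[1L],
         call. = FALSE)
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record '", ids[which(empty)[1L]], "'",
         call. = FALSE)
  }
  data.frame(protein_id = ids, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a protein set as FASTA
#'
#' @param proteome data.frame with `protein_id` and `sequence` columns.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(proteome))) {
    writeLines(paste0(">", proteome$protein_id[i]), con)
    s <- proteome$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# peptide lists -------------------------------------------------------------

#' Read a peptide list TSV
#'
#' Expects a tab-delimited file with a header row and at least a `sequence`
#' column; optional `sample_id` and `intensity` columns are carried through
#' (missing ones are filled with `NA`). Sequences are uppercased before
#' validation. Lengths are bounded to the 7-30 residue search window of the
#' upstream peptidome database search; anything outside it, or containing a
#' non-canonical letter, is invalid.
#'
#' @param path path to the TSV.
#' @param drop_invalid if `TRUE`, invalid rows are dropped with a message
#'   reporting the count; if `FALSE` (default) any invalid row is an error.
#' @return data.frame with columns `sequence`, `sample_id`, `intensity` and,
#'   if present in the file, `source_proteins`. Duplicate sequences across
#'   samples are deliberately kept as distinct records; deduplication is a
#'   downstream choice.
#' @export
read_peptide_list <- function(path, drop_invalid = FALSE) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"sequence" %in% names(tab)) {
    stop("peptide list '", path, "' lacks a 'sequence' column", call. = FALSE)
  }
  tab$sequence <- toupper(trimws(as.character(tab$sequence)))
  if (!"sample_id" %in% names(tab)) tab$sample_id <- NA_character_
  if (!"intensity" %in% names(tab)) tab$intensity <- NA_real_
  tab$intensity <- as.numeric(tab$intensity)
  ok <- is_valid_peptide(tab$sequence) &
    nchar(tab$sequence) >= 7L & nchar(tab$sequence) <= 30L
  if (any(!ok)) {
    if (drop_invalid) {
      message(sum(!ok), " invalid peptide record(s) dropped from ", path)
      tab <- tab[ok, , drop = FALSE]
      rownames(tab) <- NULL
    } else {
      stop(sum(!ok), " invalid peptide record(s) in '", path,
           "' (first: '", tab$sequence[which(!ok)[1L]],
           "'); use drop_invalid = TRUE to discard", call. = FALSE)
    }
  }
  keep <- intersect(c("sequence", "sample_id", "intensity", "source_proteins"),
                    names(tab))
  tab[, keep, drop = FALSE]
}

#' Write a peptide list TSV
#'
#' @param peptides data.frame as returned by [read_peptide_list()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peptide_list <- function(peptides, path) {
  write_tsv(peptides, path)
}

# variant tables -------------------------------------------------------------

#' Read a protein point-variant table
#'
#' Tab-delimited with header columns `gene`, `protein_id`, `position`,
#' `ref_aa`, `alt_aa` and an optional free-text `disease_label`. Positions
#' are 1-based indices into the protein sequence of the accompanying FASTA
#' (the UniProt variant-viewer convention); bounds are checked later, at scan
#' time, when the sequence is available.
#'
#' @param path path to the TSV.
#' @return validated data.frame of variants.
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  need <- c("gene", "protein_id", "position", "ref_aa", "alt_aa")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("variant table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"disease_label" %in% names(tab)) tab$disease_label <- NA_character_
  pos <- suppressWarnings(as.numeric(tab$position))
  if (any(is.na(pos)) || any(pos != floor(pos))) {
    bad <- which(is.na(pos) | pos != floor(pos))[1L]
    stop("non-integer position '", tab$position[bad], "' in variant table row ",
         bad, call. = FALSE)
  }
  tab$position <- as.integer(pos)
  tab$ref_aa <- toupper(trimws(tab$ref_aa))
  tab$alt_aa <- toupper(trimws(tab$alt_aa))
  validate_variants(tab)
  tab[, c("gene", "protein_id", "position", "ref_aa", "alt_aa",
          "disease_label")]
}

validate_variants <- function(tab) {
  aa <- aa_alphabet()
  bad_res <- !(tab$ref_aa %in% aa) | !(tab$alt_aa %in% aa)
  if (any(bad_res)) {
    stop("non-canonical residue in variant row ", which(bad_res)[1L],
         call. = FALSE)
  }
  same <- tab$ref_aa == tab$alt_aa
  if (any(same)) {
    i <- which(same)[1L]
    stop("variant ", tab$gene[i], " position ", tab$position[i],
         ": ref_aa equals alt_aa ('", tab$ref_aa[i], "')", call. = FALSE)
  }
  if (any(tab$position < 1L)) {
    stop("variant position must be >= 1", call. = FALSE)
  }
  invisible(tab)
}

#' Write a variant table TSV
#'
#' @param variants data.frame as returned by [read_variant_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  write_tsv(variants, path)
}

# shared TSV writer: tab-delimited UTF-8 with a header row, no quoting
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
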