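#' Load the packaged ADRD epitope table
#'
#' Returns the table of HLA epitopes detected in iPSC-derived microglia that
#' derive from Alzheimer's-disease-and-related-dementias risk proteins,
#' transcribed verbatim from the source study (gene symbols, disorder labels
#' and allele names exactly as printed, including the `"VPS 35"` spacing and
#' the colon-separated class II allele notation). Ranks are printed as
#' `"TOP x%"` strings; the loader parses them case-insensitively, tolerating
#' irregular whitespace, onto the 0-100 percent scale.
#'
#' Because the printed allele notation omits the usual `*` field separator,
#' the loader also returns a normalised allele name (`HLA-A11:01` ->
#' `HLA-A*11:01`, `HLA-DRB1:0101` -> `HLA-DRB1*01:01`) without guessing which
#' form any upstream pipeline used internally. Class II alpha/beta
#' heterodimers stay joined with a hyphen as one unit.
#'
#' @return data.frame with columns `gene`, `disorder`, `peptide`,
#'   `allele` (printed form), `allele_norm`, `hla_class` (`"I"`/`"II"`),
#'   `el_rank_percent`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_adrd_epitopes.tsv",
                      package = "mhcdeconv", mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "")
  need <- c("gene", "disorder", "peptide", "allele", "el_rank")
  if (!all(need %in% names(tab)) || nrow(tab) == 0L) {
    stop("packaged epitope table is corrupted: bad header or empty",
         call. = FALSE)
  }
  tab$el_rank_percent <- parse_top_rank(tab$el_rank)
  if (any(!is_valid_peptide(tab$peptide))) {
    stop("packaged epitope table is corrupted: invalid peptide",
         call. = FALSE)
  }
  if (any(tab$el_rank_percent <= 0 | tab$el_rank_percent > 100)) {
    stop("packaged epitope table is corrupted: rank out of (0, 100]",
         call. = FALSE)
  }
  tab$allele_norm <- normalize_allele(tab$allele)
  tab$hla_class <- infer_hla_class(tab$allele)
  tab[, c("gene", "disorder", "peptide", "allele", "allele_norm",
          "hla_class", "el_rank_percent")]
}

#' Parse `"TOP x%"` eluted-ligand rank labels
#'
#' @param x character vector such as `"TOP 0.89%"`, `"top 5.574 %"`.
#' @return numeric vector on the percent scale.
#' @export
parse_top_rank <- function(x) {
  m <- regmatches(x, regexec("^\\s*top\\s*([0-9]*\\.?[0-9]+)\\s*%?\\s*$",
                             x, ignore.case = TRUE))
  val <- vapply(m, function(g) {
    if (length(g) < 2L) NA_real_ else as.numeric(g[2L])
  }, numeric(1))
  if (any(is.na(val))) {
    stop("unparseable EL rank label: '", x[which(is.na(val))[1L]], "'",
         call. = FALSE)
  }
  val
}

#' Normalise printed HLA allele names
#'
#' Inserts the `*` separator and the colon between two-digit fields, e.g.
#' `HLA-A11:01` -> `HLA-A*11:01` and `HLA-DRB1:0101` -> `HLA-DRB1*01:01`.
#' Hyphen-joined class II heterodimers are normalised component-wise.
#'
#' @param allele character vector of printed names.
#' @return character vector of normalised names.
#' @export
normalize_allele <- function(allele) {
  norm_one <- function(a) {
    # split DQA1:0101-DQB1:0501 style pairs on the hyphen between components
    parts <- strsplit(a, "-(?=[A-Z])", perl = TRUE)[[1L]]
    # first part is the "HLA" prefix when present
    pre <- NULL
    if (toupper(parts[1L]) == "HLA") {
      pre <- "HLA"
      parts <- parts[-1L]
    }
    fixed <- vapply(parts, function(p) {
      # class II gene tokens end in a digit (DRB1, DQA1, ...); class I genes
      # are a single letter (A, B, C) directly followed by the allele digits
      m <- regmatches(p, regexec("^([A-Z]{2,}[0-9]):?([0-9:]+)$", p))[[1L]]
      if (length(m) == 0L) {
        m <- regmatches(p, regexec("^([A-Z]):?([0-9:]+)$", p))[[1L]]
      }
      if (length(m) == 0L) return(p)
      gene <- m[2L]
      digits <- m[3L]
      groups <- if (grepl(":", digits)) {
        strsplit(digits, ":", fixed = TRUE)[[1L]]
      } else {
        substring(digits, seq(1L, nchar(digits), 2L),
                  pmin(seq(1L, nchar(digits), 2L) + 1L, nchar(digits)))
      }
      paste0(gene, "*", paste(groups, collapse = ":"))
    }, character(1))
    paste(c(pre, fixed), collapse = "-")
  }
  vapply(allele, norm_one, character(1), USE.NAMES = FALSE)
}

#' Infer HLA class from an allele name
#'
#' @param allele character vector; names containing a class II gene token
#'   (DR, DQ, DP, DM, DO) are class II, everything else class I.
#' @return character vector of `"I"` / `"II"`.
#' @export
infer_hla_class <- function(allele) {
  ifelse(grepl("-D[RQPMO]", toupper(allele)), "II", "I")
}

#' Default allele set: the KOLF2.1J typing named in the source figures
#'
#' The subset of the KOLF2.1J iPSC line's HLA typing that the source study
#' names explicitly (its class I deconvolution alleles and the class II
#' alleles appearing in its epitope table), in the printed notation, with
#' class labels and normalised names.
#'
#' @return data.frame with columns `allele`, `allele_norm`, `hla_class`.
#' @export
kolf2_alleles <- function() {
  allele <- c("HLA-A01:01", "HLA-A11:01", "HLA-B08:01",
              "HLA-DRB1:0101", "HLA-DRB1:0404", "HLA-DPB1:1401",
              "HLA-DQA1:0101-DQB1:0501", "HLA-DQA1:0101-DQB1:0302")
  data.frame(allele = allele,
             allele_norm = normalize_allele(allele),
             hla_class = infer_hla_class(allele),
             stringsAsFactors = FALSE)
}
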