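#' Read a FASTA file with alphabet validation
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped) and validates each
#' record against the requested alphabet. Sequences are uppercased. Malformed
#' input is rejected, never silently repaired.
#'
#' @param path Path to a FASTA file.
#' @param kind Either `"nucleotide"` (A/C/G/T/N) or `"protein"` (the 20
#'   standard residues plus `X` and a terminal `*`).
#' @return A named character vector of sequences, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "acgt"), tf)
#' read_fasta(tf, "nucleotide")
#' @export
read_fasta <- function(path, kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("FASTA record with empty header in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  allowed <- switch(kind,
    nucleotide = "ACGTN",
    protein    = "ACDEFGHIKLMNPQRSTVWYX*")
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad)) {
    stop("illegal ", kind, " character in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)), all(names(seqs) != ""))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# codon -> amino acid lookup (standard code), cached
.codon_table <- function() {
  if (is.null(.arrayscan_env$codon_table)) {
    .arrayscan_env$codon_table <- Biostrings::GENETIC_CODE
  }
  .arrayscan_env$codon_table
}

.split_codons <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence under the standard genetic code
#'
#' Codons containing `N` translate to `X`. A single terminal stop codon is
#' dropped; internal stop codons are an error (intact genes only).
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @param id Identifier used in error messages.
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGGGCTAT")  # "MGY"
#' @export
translate_cds <- function(cds, id = "<cds>") {
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length of ", id, " (", nchar(cds), ") is not divisible by 3")
  }
  codons <- .split_codons(cds)
  tab <- .codon_table()
  aa <- ifelse(grepl("N", codons, fixed = TRUE), "X",
               unname(tab[codons]))
  if (anyNA(aa)) stop("unrecognized codon in ", id)
  n <- length(aa)
  if (aa[n] == "*") aa <- aa[-n]
  if (any(aa == "*")) stop("internal stop codon in ", id)
  if (length(aa) == 0L) stop("CDS of ", id, " encodes no residues")
  paste(aa, collapse = "")
}

# drop one terminal stop codon from a CDS string, if present
.trim_terminal_stop <- function(cds) {
  n <- nchar(cds)
  if (n >= 3L && n %% 3L == 0L &&
      substring(cds, n - 2L, n) %in% c("TAA", "TAG", "TGA")) {
    cds <- substring(cds, 1L, n - 3L)
  }
  cds
}

#' Build validated coding records from CDS (and optionally protein) sequences
#'
#' Pairs each CDS with its translation. Terminal stop codons are trimmed
#' before translation; internal stops, lengths not divisible by 3, and
#' mismatches against supplied proteins are hard errors. `N` codons translate
#' to `X`, and an `X` in a supplied protein is accepted wherever translation
#' yields `X`.
#'
#' @param cds Named character vector of CDS nucleotide sequences.
#' @param proteins Optional named character vector of protein sequences to
#'   cross-validate against the translations (matched by name).
#' @return A `coding_records` data frame with columns `gene_id`, `cds`
#'   (stop-trimmed), and `protein`.
#' @export
build_coding_records <- function(cds, proteins = NULL) {
  stopifnot(length(cds) > 0L, !is.null(names(cds)))
  if (anyDuplicated(names(cds))) {
    stop("duplicate gene id(s): ",
         paste(unique(names(cds)[duplicated(names(cds))]), collapse = ", "))
  }
  trimmed <- vapply(cds, .trim_terminal_stop, character(1))
  prot <- vapply(names(trimmed), function(id) {
    translate_cds(trimmed[[id]], id = id)
  }, character(1))
  if (!is.null(proteins)) {
    missing <- setdiff(names(trimmed), names(proteins))
    if (length(missing)) {
      stop("no protein supplied for: ", paste(missing, collapse = ", "))
    }
    for (id in names(trimmed)) {
      supplied <- sub("\\*$", "", toupper(proteins[[id]]))
      if (supplied != prot[[id]]) {
        stop("translation mismatch for ", id,
             ": CDS translates to '", prot[[id]],
             "' but protein is '", supplied, "'")
      }
    }
  }
  out <- data.frame(gene_id = names(trimmed),
                    cds = unname(trimmed),
                    protein = unname(prot),
                    stringsAsFactors = FALSE)
  class(out) <- c("coding_records", "data.frame")
  out
}

#' Construct coding records from already-paired sequences without translation
#' checks relaxed — still validates pairing.
#' @noRd
.as_coding_records <- function(df) {
  stopifnot(all(c("gene_id", "cds", "protein") %in% names(df)))
  class(df) <- c("coding_records", "data.frame")
  df
}
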