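#' Construct a validated gene-locus table
#'
#' Coordinates are 0-based half-open throughout the package; conversion from
#' external conventions happens only in [read_loci()].
#'
#' @param gene_id,contig Character vectors.
#' @param start,end Non-negative integers, 0-based half-open, `start < end`.
#' @param strand `"+"` or `"-"` per gene.
#' @return A `gene_loci` data frame.
#' @export
gene_loci <- function(gene_id, contig, start, end, strand) {
  df <- data.frame(gene_id = as.character(gene_id),
                   contig = as.character(contig),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene id(s) in loci")
  if (any(df$start < 0L)) stop("negative start coordinate")
  if (any(df$start >= df$end)) {
    bad <- df$gene_id[df$start >= df$end]
    stop("start >= end for: ", paste(bad, collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' (orientation analysis requires strand)")
  }
  key <- split(df$start, df$contig)
  if (any(vapply(key, anyDuplicated, integer(1)) > 0L)) {
    stop("tied start coordinates on one contig (input error)")
  }
  class(df) <- c("gene_loci", "data.frame")
  df
}

#' Read gene loci from GFF3 or BED
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention; BED passes through. Only `gene`-type GFF3 features
#' are used (feature hierarchies are out of scope). Strand is required; `.`
#' or `*` strands are rejected because orientation analysis needs them.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or 6-column BED (`.bed`) file.
#' @param format Override format detection: `"gff3"` or `"bed"`.
#' @return A `gene_loci` data frame.
#' @export
read_loci <- function(path, format = NULL) {
  if (!file.exists(path)) stop("locus file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, gff = "gff3", gff3 = "gff3", bed = "bed",
                     stop("cannot infer locus format from extension: ", ext))
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    type <- as.character(gr$type)
    gr <- gr[type == "gene"]
    if (length(gr) == 0L) stop("no gene features in ", path)
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  } else {
    ids <- as.character(gr$name)
  }
  if (is.null(ids) || anyNA(ids)) stop("locus record without a gene id in ", path)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("locus with missing strand ('.') in ", path,
         "; strand is required for orientation analysis")
  }
  # rtracklayer returns 1-based inclusive starts for both dialects
  gene_loci(gene_id = ids,
            contig = as.character(GenomeInfoDb::seqnames(gr)),
            start = BiocGenerics::start(gr) - 1L,
            end = BiocGenerics::end(gr),
            strand = strand)
}

#' Write gene loci as GFF3
#'
#' @param loci A `gene_loci` data frame (internal 0-based half-open).
#' @param path Output path; coordinates are emitted 1-based inclusive.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path, source = "arrayscan") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     loci$contig, source, loci$start + 1L, loci$end,
                     loci$strand, loci$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Construct validated alignment-hit records
#'
#' Query coordinates are 0-based half-open on the query (CNE) axis; identity
#' is a fraction in `[0, 1]`.
#'
#' @param query_id,target_id Character vectors.
#' @param query_start,query_end Integers, 0-based half-open.
#' @param percent_identity Fractions in `[0, 1]`.
#' @param score Numeric alignment scores.
#' @param strand Optional `"+"`/`"-"` per hit (default `"+"`).
#' @return A `hit_records` data frame.
#' @export
hit_records <- function(query_id, query_start, query_end, target_id,
                        percent_identity, score, strand = "+") {
  df <- data.frame(query_id = as.character(query_id),
                   query_start = as.integer(query_start),
                   query_end = as.integer(query_end),
                   target_id = as.character(target_id),
                   percent_identity = as.numeric(percent_identity),
                   score = as.numeric(score),
                   strand = rep_len(as.character(strand), length(query_id)),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$query_start < 0L) || any(df$query_start >= df$query_end)) {
      stop("hit with query_start >= query_end or negative coordinate")
    }
    if (any(df$percent_identity < 0 | df$percent_identity > 1)) {
      stop("percent_identity must be a fraction in [0, 1]")
    }
  }
  class(df) <- c("hit_records", "data.frame")
  df
}

#' Read alignment hits from a BLAST outfmt-6-like table or minimal PAF
#'
#' The 12-column tab format (`qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore`) carries 1-based inclusive query
#' coordinates and percent identities on the 0-100 scale; both are converted
#' to the internal convention (0-based half-open, fractions). PAF coordinates
#' are already 0-based half-open and identity is `nmatch / alnlen`.
#'
#' @param path Tab-separated hit file.
#' @param format `"outfmt6"` or `"paf"`.
#' @return A `hit_records` data frame.
#' @export
read_hits <- function(path, format = c("outfmt6", "paf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("hit file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (format == "outfmt6") {
    if (ncol(raw) < 12L) stop("outfmt6 table needs 12 columns, found ", ncol(raw))
    qs <- pmin(raw[[7L]], raw[[8L]])
    qe <- pmax(raw[[7L]], raw[[8L]])
    hit_records(query_id = raw[[1L]], query_start = qs - 1L, query_end = qe,
                target_id = raw[[2L]],
                percent_identity = raw[[3L]] / 100,
                score = raw[[12L]],
                strand = ifelse(raw[[9L]] <= raw[[10L]], "+", "-"))
  } else {
    if (ncol(raw) < 12L) stop("PAF needs at least 12 columns, found ", ncol(raw))
    hit_records(query_id = raw[[1L]], query_start = raw[[3L]],
                query_end = raw[[4L]], target_id = raw[[6L]],
                percent_identity = raw[[10L]] / pmax(raw[[11L]], 1L),
                score = raw[[10L]],
                strand = raw[[5L]])
  }
}
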