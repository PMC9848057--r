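.cne_status <- function(coverage, decay_cut, intact_cut) {
  ifelse(coverage < decay_cut, "decayed",
         ifelse(coverage > intact_cut, "intact", "intermediate"))
}

#' Merged alignment coverage and decay status per conserved noncoding element
#'
#' Hits below `min_identity` are discarded; the remaining query intervals of
#' each CNE are merged (union of 0-based half-open intervals) and coverage is
#' the merged length over the CNE length. Status uses strict cuts: `decayed`
#' when coverage `< decay_cut`, `intact` when coverage `> intact_cut`, else
#' `intermediate`. CNEs with no retained hit get coverage 0 (decayed).
#'
#' @param cne_lengths Named integer vector, CNE id -> length.
#' @param hits A `hit_records` data frame (see [hit_records()]).
#' @param min_identity Identity retention threshold (default 0.6).
#' @param decay_cut,intact_cut Coverage cuts (defaults 0.5 and 0.9).
#' @return A `coverage_report` data frame: `cne_id`, `cne_length`,
#'   `merged_covered`, `coverage`, `status`.
#' @export
coverage_from_hits <- function(cne_lengths, hits, min_identity = 0.6,
                               decay_cut = 0.5, intact_cut = 0.9) {
  stopifnot(!is.null(names(cne_lengths)), all(cne_lengths > 0))
  if (nrow(hits)) {
    unknown <- setdiff(hits$query_id, names(cne_lengths))
    if (length(unknown)) {
      stop("hit(s) for unknown CNE id: ", paste(unknown, collapse = ", "))
    }
    over <- hits$query_end > cne_lengths[hits$query_id]
    if (any(over)) {
      stop("hit interval exceeds declared CNE length for: ",
           paste(unique(hits$query_id[over]), collapse = ", "))
    }
    hits <- hits[hits$percent_identity >= min_identity, , drop = FALSE]
  }
  covered <- vapply(names(cne_lengths), function(id) {
    h <- hits[hits$query_id == id, , drop = FALSE]
    if (nrow(h) == 0L) return(0L)
    r <- IRanges::reduce(IRanges::IRanges(start = h$query_start + 1L,
                                          end = h$query_end))
    sum(IRanges::width(r))
  }, integer(1))
  cov <- unname(covered) / unname(cne_lengths)
  out <- data.frame(cne_id = names(cne_lengths),
                    cne_length = unname(as.integer(cne_lengths)),
                    merged_covered = unname(covered),
                    coverage = cov,
                    status = .cne_status(cov, decay_cut, intact_cut),
                    stringsAsFactors = FALSE)
  class(out) <- c("coverage_report", "data.frame")
  out
}

# one local alignment of query[qlo..qhi] against a target; recursive split
# to recover multiple non-overlapping query segments
.local_hits <- function(query, qlo, qhi, target, target_id, strand, submat,
                        gap_open, gap_extend, min_score, depth = 0L) {
  if (qhi - qlo + 1L < 10L || depth > 8L) return(NULL)
  sub <- substring(query, qlo, qhi)
  aln <- Biostrings::pairwiseAlignment(
    pattern = sub, subject = target, type = "local",
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)
  if (Biostrings::score(aln) < min_score) return(NULL)
  ps <- BiocGenerics::start(Biostrings::pattern(aln))
  pe <- BiocGenerics::end(Biostrings::pattern(aln))
  hit <- data.frame(
    query_start = qlo + ps - 2L,            # to 0-based half-open
    query_end = qlo + pe - 1L,
    target_id = target_id,
    percent_identity = Biostrings::pid(aln) / 100,
    score = Biostrings::score(aln),
    strand = strand, stringsAsFactors = FALSE)
  rbind(hit,
        .local_hits(query, qlo, qlo + ps - 2L, target, target_id, strand,
                    submat, gap_open, gap_extend, min_score, depth + 1L),
        .local_hits(query, qlo + pe, qhi, target, target_id, strand,
                    submat, gap_open, gap_extend, min_score, depth + 1L))
}

#' Desk-scale local alignment of CNEs against target sequences
#'
#' Smith-Waterman local alignment (both strands) of each CNE against each
#' target, reporting hits above `min_score` as [hit_records()]. After the
#' best local hit, the flanking query segments are re-aligned recursively so
#' that a CNE split by an internal deletion still reports both segments.
#'
#' @param cne_seqs Named character vector of CNE nucleotide sequences.
#' @param target_seqs Named character vector of target nucleotide sequences.
#' @param match,mismatch Nucleotide scores (defaults 2 and -3).
#' @param gap_open,gap_extend Gap penalties (defaults 5 and 2).
#' @param min_score Minimum reported local score (default 40; must be > 0).
#' @return A `hit_records` data frame (possibly 0 rows).
#' @export
local_align_coverage <- function(cne_seqs, target_seqs, match = 2,
                                 mismatch = -3, gap_open = 5, gap_extend = 2,
                                 min_score = 40) {
  stopifnot(length(cne_seqs) > 0L, length(target_seqs) > 0L)
  if (min_score <= 0) stop("min_score must be > 0")
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  out <- NULL
  for (qid in names(cne_seqs)) {
    q <- cne_seqs[[qid]]
    for (tid in names(target_seqs)) {
      tplus <- target_seqs[[tid]]
      tminus <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(tplus)))
      for (strand in c("+", "-")) {
        tgt <- if (strand == "+") tplus else tminus
        h <- .local_hits(q, 1L, nchar(q), tgt, tid, strand, submat,
                         gap_open, gap_extend, min_score)
        if (!is.null(h)) {
          h <- data.frame(query_id = qid, h, stringsAsFactors = FALSE)
          out <- rbind(out, h)
        }
      }
    }
  }
  if (is.null(out)) {
    return(hit_records(character(0), integer(0), integer(0), character(0),
                       numeric(0), numeric(0), character(0)))
  }
  hit_records(out$query_id, out$query_start, out$query_end, out$target_id,
              out$percent_identity, out$score, out$strand)
}

#' Cross-species CNE decay contrast
#'
#' Flags CNEs decayed in a focal species while intact in every other
#' species, and (optionally) reports the decayed fraction per region label
#' in the focal species.
#'
#' @param reports_by_species Named list of `coverage_report` data frames,
#'   all over the same CNE ids.
#' @param focal Name of the focal species (default: first list element).
#' @param region_labels Optional named character vector CNE id -> region.
#' @return A list with `table` (per-CNE coverages, `flagged` boolean) and
#'   `region_decay` (data frame of region, n, decayed fraction; `NULL`
#'   without labels).
#' @export
decay_contrast <- function(reports_by_species, focal = NULL,
                           region_labels = NULL) {
  stopifnot(is.list(reports_by_species), length(reports_by_species) >= 2L,
            !is.null(names(reports_by_species)))
  if (is.null(focal)) focal <- names(reports_by_species)[1L]
  if (!focal %in% names(reports_by_species)) stop("unknown focal species: ", focal)
  ids <- sort(reports_by_species[[focal]]$cne_id)
  for (sp in names(reports_by_species)) {
    if (!setequal(reports_by_species[[sp]]$cne_id, ids)) {
      stop("CNE ids of species '", sp, "' differ from focal species")
    }
  }
  pull <- function(sp, col) {
    r <- reports_by_species[[sp]]
    r[match(ids, r$cne_id), col]
  }
  others <- setdiff(names(reports_by_species), focal)
  others_intact <- Reduce(`&`, lapply(others, function(sp) {
    pull(sp, "status") == "intact"
  }))
  tab <- data.frame(cne_id = ids,
                    focal_coverage = pull(focal, "coverage"),
                    focal_status = pull(focal, "status"),
                    others_intact = others_intact,
                    flagged = pull(focal, "status") == "decayed" & others_intact,
                    stringsAsFactors = FALSE)
  for (sp in others) tab[[paste0("coverage_", sp)]] <- pull(sp, "coverage")
  region_decay <- NULL
  if (!is.null(region_labels)) {
    reg <- region_labels[ids]
    if (anyNA(reg)) stop("region label missing for some CNE id(s)")
    region_decay <- do.call(rbind, lapply(unique(reg), function(r) {
      sel <- reg == r
      data.frame(region = r, n = sum(sel),
                 decayed_fraction = mean(tab$focal_status[sel] == "decayed"),
                 stringsAsFactors = FALSE)
    }))
  }
  list(table = tab, region_decay = region_decay)
}
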