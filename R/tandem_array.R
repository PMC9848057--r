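#' Partition genes into identical-CDS clades
#'
#' Groups coding records by exact CDS string equality (the strict criterion
#' behind "identical paralogs"); a relaxed mode groups genes whose pairwise
#' protein identity is at least `identity_threshold` via single linkage.
#'
#' @param records A `coding_records` data frame.
#' @param mode `"exact"` (default) or `"identity"`.
#' @param identity_threshold Protein-identity threshold for the relaxed mode
#'   (default 0.99).
#' @return A list of character vectors of gene ids (clades, largest first).
#' @export
identical_cds_clades <- function(records, mode = c("exact", "identity"),
                                 identity_threshold = 0.99) {
  mode <- match.arg(mode)
  if (mode == "exact") {
    cl <- split(records$gene_id, factor(records$cds))
  } else {
    n <- nrow(records)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        aln <- align_proteins(records$protein[i], records$protein[j])
        if (aln$identity >= identity_threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    cl <- split(records$gene_id, roots)
  }
  cl <- unname(cl)
  cl[order(-vapply(cl, length, integer(1)))]
}

#' Neighbor-identity profile of a tandem gene array
#'
#' Orders genes by locus start on their contig, aligns each adjacent pair of
#' proteins, and summarizes homogenization: per-pair identity
#' (1 - p-distance over gap-free columns), mean neighbor identity,
#' tail-to-head orientation (all strands equal along the run), and
#' identical-CDS clades.
#'
#' @param records A `coding_records` data frame.
#' @param loci A `gene_loci` data frame covering every analyzed gene; all
#'   analyzed genes must lie on a single contig.
#' @param family_filter Optional character vector restricting the analysis
#'   to a gene subset (e.g. one KRTAP family).
#' @param ... Passed to [align_proteins()].
#' @return An `array_report` list: `contig`, `ordered_genes`,
#'   `neighbor_identities`, `mean_neighbor_identity`, `tail_to_head`,
#'   `clades`, `clade_sizes`.
#' @export
neighbor_identity_profile <- function(records, loci, family_filter = NULL,
                                      ...) {
  genes <- records$gene_id
  if (!is.null(family_filter)) genes <- intersect(genes, family_filter)
  if (length(genes) < 2L) stop("array analysis needs at least 2 genes")
  missing <- setdiff(genes, loci$gene_id)
  if (length(missing)) {
    stop("gene(s) without locus: ", paste(missing, collapse = ", "))
  }
  loc <- loci[match(genes, loci$gene_id), ]
  contigs <- unique(loc$contig)
  if (length(contigs) > 1L) {
    stop("array genes span multiple contigs (one contig per report): ",
         paste(contigs, collapse = ", "))
  }
  ord <- order(loc$start)
  loc <- loc[ord, ]
  if (any(loc$end[-nrow(loc)] > loc$start[-1L])) {
    warning("overlapping loci in array; order by start retained")
  }
  rec <- records[match(loc$gene_id, records$gene_id), ]
  ids <- rec$gene_id
  idents <- vapply(seq_len(length(ids) - 1L), function(k) {
    align_proteins(rec$protein[k], rec$protein[k + 1L], ...)$identity
  }, numeric(1))
  names(idents) <- paste(ids[-length(ids)], ids[-1L], sep = "|")
  clades <- identical_cds_clades(rec)
  structure(list(contig = contigs,
                 ordered_genes = ids,
                 neighbor_identities = idents,
                 mean_neighbor_identity = mean(idents),
                 tail_to_head = length(unique(loc$strand)) == 1L,
                 clades = clades,
                 clade_sizes = vapply(clades, length, integer(1))),
            class = "array_report")
}

#' @export
print.array_report <- function(x, ...) {
  cat("array_report:", length(x$ordered_genes), "genes on", x$contig, "\n",
      " mean neighbor identity:", format(x$mean_neighbor_identity), "\n",
      " tail-to-head:", x$tail_to_head,
      "; clades:", paste(x$clade_sizes, collapse = "+"), "\n")
  invisible(x)
}

#' One-way ANOVA over neighbor-identity samples of several arrays
#'
#' @param ... Two or more `array_report` objects (or a single list of them),
#'   each contributing at least 2 neighbor identities.
#' @return A list with `F`, `df` (between, within), `p_value`, and
#'   `group_means`.
#' @export
compare_arrays <- function(...) {
  reports <- list(...)
  if (length(reports) == 1L && !inherits(reports[[1L]], "array_report")) {
    reports <- reports[[1L]]
  }
  if (length(reports) < 2L) stop("need at least 2 arrays to compare")
  sizes <- vapply(reports, function(r) length(r$neighbor_identities), integer(1))
  if (any(sizes < 2L)) {
    stop("every array must contribute >= 2 neighbor identities")
  }
  values <- unlist(lapply(reports, `[[`, "neighbor_identities"), use.names = FALSE)
  labels <- if (!is.null(names(reports)) && all(nzchar(names(reports)))) {
    names(reports)
  } else paste0("array", seq_along(reports))
  groups <- rep(labels, sizes)
  a <- .one_way_anova(values, groups)
  a$group_means <- tapply(values, groups, mean)
  a
}

#' Within- and between-clade Ks summary with clock dating
#'
#' Mean pairwise NG86 Ks over unordered pairs within each clade and over all
#' cross pairs between the two clades; saturated pairs (undefined Ks) are
#' excluded and counted. Mean divergence times use `T = Ks / (2 mu)`.
#'
#' @param records A `coding_records` data frame containing every clade
#'   member.
#' @param clade_a,clade_b Character vectors of gene ids; disjoint. `clade_b`
#'   may be `NULL` for a within-only summary.
#' @param mu Clock rate (default `2e-9` per site per year).
#' @param ... Passed to [ng86_ks()].
#' @return A list with components `within_a`, `within_b`, `between`, each a
#'   list of `mean_ks`, `mean_t`, `n_pairs`, `n_saturated`, `ks` (vector);
#'   within summaries are `NULL` for clades of size < 2.
#' @export
clade_ks_summary <- function(records, clade_a, clade_b = NULL, mu = 2e-9,
                             ...) {
  if (length(intersect(clade_a, clade_b))) stop("clades must be disjoint")
  missing <- setdiff(c(clade_a, clade_b), records$gene_id)
  if (length(missing)) {
    stop("clade gene(s) missing from records: ", paste(missing, collapse = ", "))
  }
  get <- function(id) records[match(id, records$gene_id), ]
  pair_ks <- function(pairs) {
    ks <- vapply(seq_len(ncol(pairs)), function(k) {
      ng86_ks(get(pairs[1L, k]), get(pairs[2L, k]), mu = mu, ...)$Ks
    }, numeric(1))
    ok <- !is.na(ks)
    list(mean_ks = if (any(ok)) mean(ks[ok]) else NA_real_,
         mean_t = if (any(ok)) divergence_time(mean(ks[ok]), mu) else NA_real_,
         n_pairs = ncol(pairs), n_saturated = sum(!ok), ks = ks[ok])
  }
  within <- function(clade) {
    if (length(clade) < 2L) return(NULL)
    pair_ks(utils::combn(clade, 2L))
  }
  between <- if (length(clade_a) && length(clade_b)) {
    pair_ks(rbind(rep(clade_a, each = length(clade_b)),
                  rep(clade_b, times = length(clade_a))))
  } else NULL
  list(within_a = within(clade_a), within_b = within(clade_b),
       between = between, mu = mu)
}
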