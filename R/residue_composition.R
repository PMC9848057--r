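.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Residue and nucleotide composition of a coding record
#'
#' Amino-acid proportions are computed over the 20 standard residues; `X`
#' (unknown) is excluded from both numerator and denominator. GC content is
#' computed over the unambiguous A/C/G/T of the CDS; GC at third codon
#' positions (GC3) is reported alongside.
#'
#' @param records A `coding_records` data frame (see [build_coding_records()]).
#' @return A data frame of class `composition_profiles` with one row per gene:
#'   per-residue proportions (columns `A` ... `Y`), `gly`, `tyr`, `gly_tyr`,
#'   `gc`, `gc3`.
#' @examples
#' rec <- build_coding_records(c(g1 = "GGCTATGGATAC"))
#' composition(rec)[, c("gly", "tyr", "gly_tyr")]
#' @export
composition <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("gene_id", "cds", "protein") %in% names(records)))
  prof <- t(vapply(seq_len(nrow(records)), function(i) {
    aa <- strsplit(records$protein[i], "")[[1]]
    aa <- aa[aa != "X"]
    if (length(aa) == 0L) {
      stop("empty protein after X exclusion for ", records$gene_id[i])
    }
    counts <- table(factor(aa, levels = .AA20))
    p <- as.numeric(counts) / length(aa)
    nt <- strsplit(records$cds[i], "")[[1]]
    acgt <- nt[nt %in% c("A", "C", "G", "T")]
    gc <- if (length(acgt)) mean(acgt %in% c("G", "C")) else NA_real_
    third <- nt[seq(3L, length(nt), by = 3L)]
    third <- third[third %in% c("A", "C", "G", "T")]
    gc3 <- if (length(third)) mean(third %in% c("G", "C")) else NA_real_
    c(p, gc = gc, gc3 = gc3)
  }, numeric(length(.AA20) + 2L)))
  colnames(prof) <- c(.AA20, "gc", "gc3")
  out <- data.frame(gene_id = records$gene_id, prof,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$gly <- out$G
  out$tyr <- out$Y
  out$gly_tyr <- out$G + out$Y
  class(out) <- c("composition_profiles", "data.frame")
  out
}

#' Tyrosine-rich, expression-anchored candidate screen
#'
#' Selects genes whose tyrosine proportion is at least `tyr_cutoff` and whose
#' expression class is anchored on `anchor_tissue` (tissue-enriched there, or
#' group-enriched with the anchor in the group). Optionally tallies the
#' selection by user-supplied family labels.
#'
#' @param profiles A `composition_profiles` data frame.
#' @param classes An `expression_classes` data frame covering every profiled
#'   gene.
#' @param tyr_cutoff Tyrosine-fraction cutoff (default 0.05, i.e. 5%).
#' @param anchor_tissue Anchor tissue id (default `"skin"`).
#' @param family_labels Optional named character vector gene_id -> family.
#' @return A list with `genes` (selected gene ids) and `family_counts`
#'   (named integer vector; empty when no labels given).
#' @export
tyrosine_screen <- function(profiles, classes, tyr_cutoff = 0.05,
                            anchor_tissue = "skin", family_labels = NULL) {
  missing <- setdiff(profiles$gene_id, classes$gene_id)
  if (length(missing)) {
    stop("gene(s) in profiles missing from classes: ",
         paste(missing, collapse = ", "))
  }
  related <- skin_related_set(classes, anchor_tissue)$genes
  sel <- profiles$gene_id[profiles$tyr >= tyr_cutoff &
                          profiles$gene_id %in% related]
  fam <- if (is.null(family_labels) || length(sel) == 0L) {
    stats::setNames(integer(0), character(0))
  } else {
    lab <- family_labels[sel]
    lab[is.na(lab)] <- "unlabelled"
    tab <- sort(table(lab), decreasing = TRUE)
    stats::setNames(as.integer(tab), names(tab))
  }
  list(genes = sel, family_counts = fam)
}

# classic one-way ANOVA from group-labelled values
.one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  if (k < 2L) stop("ANOVA needs at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    stop("ANOVA needs >= 2 members per group; offending group(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- k - 1L; df2 <- n - k
  msb <- ssb / df1; msw <- ssw / df2
  f <- if (msw == 0) {
    if (msb == 0) 0 else Inf
  } else msb / msw
  p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
  list(F = unname(f), df = c(df1, df2), p_value = unname(p))
}

#' Per-group composition means with one-way ANOVA
#'
#' Summarizes `gly`, `tyr`, `gly_tyr`, and `gc` by group (species or gene
#' family) and tests each metric across groups with a classic one-way ANOVA
#' (F from between/within mean squares). With a single group, means are
#' returned and the ANOVA is refused (`NA` statistics).
#'
#' @param profiles A `composition_profiles` data frame.
#' @param groups Character vector of group labels, one per profile row.
#' @param metrics Metrics to summarize (default the four above).
#' @return A list with `means` (group x metric data frame) and `anova`
#'   (metric-indexed data frame of `F`, `df1`, `df2`, `p_value`).
#' @export
group_composition_summary <- function(profiles, groups,
                                      metrics = c("gly", "tyr", "gly_tyr", "gc")) {
  stopifnot(length(groups) == nrow(profiles))
  groups <- factor(groups)
  means <- do.call(rbind, lapply(levels(groups), function(g) {
    sub <- profiles[groups == g, metrics, drop = FALSE]
    data.frame(group = g, n = nrow(sub), t(colMeans(sub)),
               stringsAsFactors = FALSE)
  }))
  anova <- if (nlevels(groups) < 2L) {
    data.frame(metric = metrics, F = NA_real_, df1 = NA_integer_,
               df2 = NA_integer_, p_value = NA_real_,
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(metrics, function(m) {
      a <- .one_way_anova(profiles[[m]], groups)
      data.frame(metric = m, F = a$F, df1 = a$df[1], df2 = a$df[2],
                 p_value = a$p_value, stringsAsFactors = FALSE)
    }))
  }
  list(means = means, anova = anova)
}
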