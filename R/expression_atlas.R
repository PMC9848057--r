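#' Classify genes into tissue-specificity categories
#'
#' Human-Protein-Atlas-style three-way classification on a genes-by-tissues
#' TPM matrix. Rules are evaluated in order:
#'
#' 1. `not_detected`: TPM below `detect_threshold` in every tissue.
#' 2. `tissue_enriched`: the highest tissue is at least `fold_threshold`
#'    times the second-highest ("at least" read as `>=`; a second-highest of
#'    exactly 0 with a positive maximum counts as infinite fold).
#' 3. `group_enriched`: the candidate group is exactly the set of tissues
#'    with per-gene Z-score `>= z_threshold` (Z over raw TPM across tissues);
#'    it qualifies when its size is in `[2, group_max]` and its mean TPM is
#'    at least `fold_threshold` times the mean TPM of all remaining tissues.
#' 4. `other` otherwise.
#'
#' @param matrix An `expr_matrix` (see [expression_matrix()]).
#' @param fold_threshold Enrichment fold threshold (default 5).
#' @param detect_threshold Detection TPM threshold (default 1).
#' @param z_threshold Z-score threshold for group membership (default 1).
#' @param group_max Maximum group size considered (default 7).
#' @param log_z If `TRUE`, compute Z-scores on `log2(TPM + 1)` instead of raw
#'   TPM (off by default).
#' @return A data frame of class `expression_classes` with columns `gene_id`,
#'   `category`, `focus_tissues` (comma-separated, empty when none), and
#'   `fold` (achieved enrichment ratio; `Inf` sentinel allowed; `NA` for
#'   `not_detected`/`other`).
#' @export
classify_genes <- function(matrix, fold_threshold = 5, detect_threshold = 1,
                           z_threshold = 1, group_max = 7L, log_z = FALSE) {
  stopifnot(inherits(matrix, "expr_matrix"))
  tpm <- matrix$tpm
  if (ncol(tpm) < 3L) {
    stop("classification needs at least 3 tissues (group rule needs a complement)")
  }
  tissues <- colnames(tpm)
  res <- lapply(seq_len(nrow(tpm)), function(i) {
    x <- tpm[i, ]
    if (all(x < detect_threshold)) {
      return(list(category = "not_detected", focus = character(0), fold = NA_real_))
    }
    ord <- order(x, decreasing = TRUE)
    top <- x[ord[1L]]; second <- x[ord[2L]]
    fold <- if (second == 0) {
      if (top > 0) Inf else NA_real_
    } else top / second
    if (!is.na(fold) && fold >= fold_threshold) {
      return(list(category = "tissue_enriched", focus = tissues[ord[1L]],
                  fold = fold))
    }
    zx <- if (log_z) log2(x + 1) else x
    s <- stats::sd(zx)
    if (is.finite(s) && s > 0) {
      z <- (zx - mean(zx)) / s
      grp <- which(z >= z_threshold)
      if (length(grp) >= 2L && length(grp) <= group_max) {
        gmean <- mean(x[grp]); omean <- mean(x[-grp])
        gfold <- if (omean == 0) {
          if (gmean > 0) Inf else NA_real_
        } else gmean / omean
        if (!is.na(gfold) && gfold >= fold_threshold) {
          return(list(category = "group_enriched",
                      focus = tissues[sort(grp)], fold = gfold))
        }
      }
    }
    list(category = "other", focus = character(0), fold = NA_real_)
  })
  out <- data.frame(
    gene_id = rownames(tpm),
    category = vapply(res, `[[`, character(1), "category"),
    focus_tissues = vapply(res, function(r) paste(r$focus, collapse = ","),
                           character(1)),
    fold = vapply(res, `[[`, numeric(1), "fold"),
    stringsAsFactors = FALSE)
  class(out) <- c("expression_classes", "data.frame")
  out
}

#' Genes with expression anchored on one tissue
#'
#' Returns genes that are either tissue-enriched on `anchor_tissue` or
#' group-enriched with `anchor_tissue` in their focus group, together with a
#' tally of co-expression partner tissues among the group-enriched members.
#'
#' @param classes An `expression_classes` data frame.
#' @param anchor_tissue Tissue id (e.g. `"skin"`).
#' @param tissues Optional character vector of valid tissue ids; when given,
#'   an unknown `anchor_tissue` is an error.
#' @return A list with `genes` (character vector) and `partner_counts`
#'   (named integer vector of co-expressed tissues and gene counts).
#' @export
skin_related_set <- function(classes, anchor_tissue, tissues = NULL) {
  stopifnot(is.data.frame(classes))
  if (!is.null(tissues) && !anchor_tissue %in% tissues) {
    stop("unknown tissue id: ", anchor_tissue)
  }
  focus <- strsplit(classes$focus_tissues, ",", fixed = TRUE)
  anchored <- vapply(focus, function(f) anchor_tissue %in% f, logical(1))
  keep <- anchored & classes$category %in% c("tissue_enriched", "group_enriched")
  genes <- classes$gene_id[keep]
  grp <- keep & classes$category == "group_enriched"
  partners <- unlist(lapply(focus[grp], setdiff, y = anchor_tissue))
  counts <- if (length(partners)) sort(table(partners), decreasing = TRUE)
            else table(character(0))
  list(genes = genes,
       partner_counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Differential expression screen between two replicate groups
#'
#' Per-gene Welch's t-test on `log2(TPM + 1)` between the two sides, with
#' Benjamini-Hochberg adjustment across all tested genes. Fold change is the
#' ratio of replicate means of `TPM + 1` (pseudocount avoids division by
#' zero). A gene passes the screen when `|fold change| > fold_cut`, adjusted
#' P `< alpha`, and it belongs to the anchor-tissue-related expression set.
#'
#' @param matrix_A,matrix_B Numeric matrices of TPM, genes x replicates, with
#'   identical rownames and `>= 2` columns each.
#' @param classes An `expression_classes` data frame (see [classify_genes()]).
#' @param fold_cut Fold-change cutoff (default 2, applied strictly).
#' @param alpha Adjusted-P cutoff (default 0.05, applied strictly).
#' @param anchor_tissue Tissue anchoring the "related" filter (default
#'   `"skin"`).
#' @return A data frame of class `differential_results`: `gene_id`,
#'   `log2_fold_change` (A over B), `p_value`, `adjusted_p`, `passes_screen`,
#'   `direction` (`"up_in_A"`/`"up_in_B"`/`"none"`).
#' @export
differential_screen <- function(matrix_A, matrix_B, classes, fold_cut = 2,
                                alpha = 0.05, anchor_tissue = "skin") {
  stopifnot(is.matrix(matrix_A), is.matrix(matrix_B))
  if (ncol(matrix_A) < 2L || ncol(matrix_B) < 2L) {
    stop("each side needs at least 2 replicates")
  }
  if (!identical(rownames(matrix_A), rownames(matrix_B))) {
    stop("the two sides must share identical gene rownames")
  }
  genes <- rownames(matrix_A)
  la <- log2(matrix_A + 1); lb <- log2(matrix_B + 1)
  pv <- numeric(length(genes))
  for (i in seq_along(genes)) {
    a <- la[i, ]; b <- lb[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      pv[i] <- 1  # no within-group evidence
    } else {
      pv[i] <- stats::t.test(a, b)$p.value
    }
  }
  padj <- stats::p.adjust(pv, method = "BH")
  fc <- rowMeans(matrix_A + 1) / rowMeans(matrix_B + 1)
  l2fc <- log2(fc)
  related <- genes %in% skin_related_set(classes, anchor_tissue)$genes
  passes <- (fc > fold_cut | fc < 1 / fold_cut) & padj < alpha & related
  out <- data.frame(
    gene_id = genes,
    log2_fold_change = unname(l2fc),
    p_value = pv,
    adjusted_p = padj,
    passes_screen = unname(passes),
    direction = ifelse(!passes, "none",
                       ifelse(l2fc > 0, "up_in_A", "up_in_B")),
    stringsAsFactors = FALSE)
  class(out) <- c("differential_results", "data.frame")
  out
}
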