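# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: the aligner oracle is a top-down recursion over
# suffixes, interval merging marks individual bases, and the group-enrichment
# oracle enumerates every candidate tissue subset.

# --- affine-gap global alignment score, top-down over suffixes -------------
# gap of length L costs open + ext * L; states track whether the previous
# column opened a gap in a or in b (for extension pricing)
oracle_nw_score <- function(a, b, submat, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, submat[av[i], bv[j]] + rec(i + 1L, j + 1L, "none"))
    }
    if (i <= n) {  # a[i] against a gap in b
      pen <- if (prev == "gap_b") ext else open + ext
      best <- max(best, -pen + rec(i + 1L, j, "gap_b"))
    }
    if (j <= m) {  # gap in a against b[j]
      pen <- if (prev == "gap_a") ext else open + ext
      best <- max(best, -pen + rec(i, j + 1L, "gap_a"))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, "none")
}

# --- interval union by brute-force base marking ----------------------------
oracle_merged_bases <- function(starts, ends, len) {
  hit <- logical(len)
  for (k in seq_along(starts)) {
    if (ends[k] > starts[k]) hit[(starts[k] + 1L):ends[k]] <- TRUE
  }
  sum(hit)
}

# --- exhaustive evaluation of the expression classification rules ----------
oracle_classify_one <- function(x, fold = 5, detect = 1, zth = 1,
                                group_max = 7L) {
  tissues <- names(x)
  if (all(x < detect)) return(list(category = "not_detected", focus = character(0)))
  srt <- sort(x, decreasing = TRUE)
  if (srt[2] == 0) {
    if (srt[1] > 0) return(list(category = "tissue_enriched",
                                focus = names(srt)[1]))
  } else if (srt[1] / srt[2] >= fold) {
    return(list(category = "tissue_enriched", focus = names(srt)[1]))
  }
  s <- sd(x)
  if (is.finite(s) && s > 0) {
    z <- (x - mean(x)) / s
    for (size in 2:min(group_max, length(x) - 1L)) {
      for (grp in combn(seq_along(x), size, simplify = FALSE)) {
        if (all(z[grp] >= zth) && all(z[-grp] < zth)) {
          om <- mean(x[-grp])
          ratio <- if (om == 0) {
            if (mean(x[grp]) > 0) Inf else NA_real_
          } else mean(x[grp]) / om
          if (!is.na(ratio) && ratio >= fold) {
            return(list(category = "group_enriched",
                        focus = sort(tissues[grp])))
          }
        }
      }
    }
  }
  list(category = "other", focus = character(0))
}

# --- small shared fixtures -------------------------------------------------
toy_matrix <- function(values, tissues) {
  expression_matrix(matrix(values, nrow = 1,
                           dimnames = list("g1", tissues)))
}

random_protein <- function(n, alphabet = c("G", "Y", "C", "A", "S")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
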