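# Global protein alignment (Gotoh affine-gap dynamic programming) and
# p-distance. A gap of length L costs gap_open + gap_extend * L. Among
# equal-scoring tracebacks the preference is match/mismatch, then gap in
# `a`, then gap in `b`, giving deterministic output.

.scoring_matrix <- function(name) {
  key <- paste0("submat_", name)
  if (is.null(.arrayscan_env[[key]])) {
    ok <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
            "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
    if (!name %in% ok) stop("unknown substitution matrix: ", name)
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .arrayscan_env[[key]] <- e[[name]]
  }
  .arrayscan_env[[key]]
}

#' Global pairwise protein alignment with affine gap penalties
#'
#' Needleman-Wunsch / Gotoh alignment under a named substitution matrix.
#' A gap of length L is penalized `gap_open + gap_extend * L`. The
#' p-distance is the fraction of mismatched columns among columns where
#' neither sequence has a gap; identity is its complement.
#'
#' @param a,b Protein sequences (non-empty strings over the 20 residues
#'   plus `X`).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Gap penalties (defaults 11 and 1).
#' @return A `pairwise_alignment` list: `aligned_a`, `aligned_b` (equal
#'   length, `-` for gaps), `score`, `p_distance`, `identity`.
#' @examples
#' align_proteins("GYGGY", "GYGAY")$p_distance  # 0.2
#' @export
align_proteins <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  S <- .scoring_matrix(matrix)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  bad <- setdiff(c(av, bv), rownames(S))
  if (length(bad)) stop("residue(s) not in ", matrix, ": ",
                        paste(bad, collapse = ", "))
  n <- length(av); m <- length(bv)
  oe <- gap_open + gap_extend; e <- gap_extend
  NEG <- -1e9
  # state matrices, (n+1) x (m+1); row/col 1 is the empty prefix
  M  <- matrix(NEG, n + 1L, m + 1L)  # a[i] aligned to b[j]
  Ix <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes b)
  M[1L, 1L] <- 0
  if (n) Ix[2L:(n + 1L), 1L] <- -(gap_open + e * seq_len(n))
  if (m) Iy[1L, 2L:(m + 1L)] <- -(gap_open + e * seq_len(m))
  for (i in 2L:(n + 1L)) {
    srow <- S[av[i - 1L], bv]
    pM <- M[i - 1L, ]; pIx <- Ix[i - 1L, ]; pIy <- Iy[i - 1L, ]
    if (m) {
      M[i, 2L:(m + 1L)] <- pmax(pM[1L:m], pIx[1L:m], pIy[1L:m]) + srow
      Ix[i, ] <- pmax(pM - oe, pIx - e, pIy - oe)
      Ix[i, 1L] <- Ix[i, 1L]  # column 1 set by init above
      for (j in 2L:(m + 1L)) {
        Iy[i, j] <- max(M[i, j - 1L] - oe, Ix[i, j - 1L] - oe,
                        Iy[i, j - 1L] - e)
      }
    } else {
      Ix[i, 1L] <- max(pM[1L] - oe, pIx[1L] - e, pIy[1L] - oe)
    }
  }
  # deterministic state preference: M, then Iy (gap in a), then Ix (gap in b)
  pick <- function(mv, ixv, iyv) {
    if (mv >= ixv && mv >= iyv) "M" else if (iyv >= ixv) "Iy" else "Ix"
  }
  i <- n + 1L; j <- m + 1L
  state <- pick(M[i, j], Ix[i, j], Iy[i, j])
  score <- max(M[i, j], Ix[i, j], Iy[i, j])
  out_a <- character(0); out_b <- character(0)
  while (i > 1L || j > 1L) {
    if (state == "M") {
      out_a <- c(av[i - 1L], out_a); out_b <- c(bv[j - 1L], out_b)
      i <- i - 1L; j <- j - 1L
      state <- pick(M[i, j], Ix[i, j], Iy[i, j])
    } else if (state == "Ix") {   # gap in b
      out_a <- c(av[i - 1L], out_a); out_b <- c("-", out_b)
      val <- Ix[i, j]; i <- i - 1L
      state <- if (isTRUE(all.equal(val, M[i, j] - oe))) "M"
               else if (isTRUE(all.equal(val, Iy[i, j] - oe))) "Iy" else "Ix"
    } else {                      # Iy: gap in a
      out_a <- c("-", out_a); out_b <- c(bv[j - 1L], out_b)
      val <- Iy[i, j]; j <- j - 1L
      state <- if (isTRUE(all.equal(val, M[i, j] - oe))) "M"
               else if (isTRUE(all.equal(val, Ix[i, j] - oe))) "Ix" else "Iy"
    }
  }
  aligned_a <- paste(out_a, collapse = "")
  aligned_b <- paste(out_b, collapse = "")
  pd <- p_distance(aligned_a, aligned_b)
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = score, p_distance = pd, identity = 1 - pd),
            class = "pairwise_alignment")
}

#' p-distance over gap-free columns of an alignment
#'
#' @param aligned_a,aligned_b Equal-length aligned strings (`-` = gap).
#' @return Fraction of mismatched columns among columns where neither
#'   sequence has a gap; `NA` if no such column exists.
#' @export
p_distance <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned strings must have equal length")
  }
  ca <- strsplit(aligned_a, "")[[1]]; cb <- strsplit(aligned_b, "")[[1]]
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) return(NA_real_)
  mean(ca[keep] != cb[keep])
}
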