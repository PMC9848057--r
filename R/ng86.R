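# Nei-Gojobori (1986) synonymous/nonsynonymous substitution estimation with
# Jukes-Cantor multiple-hit correction, plus molecular-clock dating.
#
# Site counting: at each codon position the synonymous site fraction is the
# share of the 3 possible single-nucleotide changes that preserve the amino
# acid; changes creating a stop codon count as nonsynonymous, so S + N is
# exactly 3 per compared codon. Codons differing at several positions are
# scored by averaging over all minimal substitution pathways with equal
# weights, excluding pathways that pass through a stop codon.

.BASES <- c("A", "C", "G", "T")

.sense_codons <- function() {
  tab <- .codon_table()
  names(tab)[tab != "*"]
}

# named vector: sense codon -> synonymous sites (0..3)
.syn_sites_table <- function() {
  if (is.null(.arrayscan_env$syn_sites)) {
    tab <- .codon_table()
    sense <- .sense_codons()
    syn <- vapply(sense, function(cod) {
      aa <- tab[[cod]]
      chars <- strsplit(cod, "")[[1]]
      total <- 0
      for (pos in 1:3) {
        alts <- setdiff(.BASES, chars[pos])
        nsyn <- 0L
        for (b in alts) {
          mut <- chars; mut[pos] <- b
          if (tab[[paste(mut, collapse = "")]] == aa) nsyn <- nsyn + 1L
        }
        total <- total + nsyn / 3
      }
      total
    }, numeric(1))
    .arrayscan_env$syn_sites <- syn
  }
  .arrayscan_env$syn_sites
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

# average (Sd, Nd) over all minimal pathways between two sense codons;
# returns NULL when every pathway crosses a stop codon
.codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  tab <- .codon_table()
  x1 <- strsplit(c1, "")[[1]]; x2 <- strsplit(c2, "")[[1]]
  dpos <- which(x1 != x2)
  paths <- .permutations(dpos)
  acc <- matrix(NA_real_, nrow = 0, ncol = 2)
  for (p in paths) {
    cur <- x1; sd <- 0; nd <- 0; ok <- TRUE
    for (pos in p) {
      nxt <- cur; nxt[pos] <- x2[pos]
      aa_cur <- tab[[paste(cur, collapse = "")]]
      aa_nxt <- tab[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*") { ok <- FALSE; break }
      if (aa_nxt == aa_cur) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) acc <- rbind(acc, c(sd, nd))
  }
  if (nrow(acc) == 0L) return(NULL)
  c(sd = mean(acc[, 1]), nd = mean(acc[, 2]))
}

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 3 / 4) return(NA_real_)
  -(3 / 4) * log(1 - (4 / 3) * p)
}

#' Nei-Gojobori (1986) Ks/Ka estimate for a pair of coding records
#'
#' The two CDS are codon-aligned by globally aligning their proteins
#' ([align_proteins()]) and threading the gaps back onto the nucleotide
#' sequences; columns with a gap in either sequence are dropped pairwise, as
#' are codon pairs containing `N` or a stop. Proportions are corrected for
#' multiple hits with the Jukes-Cantor formula
#' `Ks = -(3/4) ln(1 - (4/3) pS)`; `pS >= 3/4` is reported as saturated
#' (`Ks = NA`). Divergence time is `T = Ks / (2 mu)` under a molecular
#' clock.
#'
#' @param a,b Single coding records (one-row subsets of a `coding_records`
#'   data frame, or lists with `gene_id`, `cds`, `protein`).
#' @param mu Clock rate in substitutions per site per year (default `2e-9`).
#' @param ... Passed to [align_proteins()].
#' @return A `ks_estimate` list: `id_a`, `id_b`, `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `Ks`, `Ka`, `mu`, `T` (years), `saturated`, `codons_compared`,
#'   `codons_excluded` (N/stop codons), `paths_blocked` (pairs whose every
#'   pathway crosses a stop).
#' @export
ng86_ks <- function(a, b, mu = 2e-9, ...) {
  stopifnot(!is.null(a$cds), !is.null(b$cds))
  aln <- align_proteins(a$protein, b$protein, ...)
  ca_all <- .split_codons(a$cds)
  cb_all <- .split_codons(b$cds)
  va <- strsplit(aln$aligned_a, "")[[1]]
  vb <- strsplit(aln$aligned_b, "")[[1]]
  ia <- cumsum(va != "-"); ib <- cumsum(vb != "-")
  both <- va != "-" & vb != "-"
  pair_a <- ca_all[ia[both]]; pair_b <- cb_all[ib[both]]

  syn <- .syn_sites_table(); sense <- names(syn)
  usable <- pair_a %in% sense & pair_b %in% sense &
            !grepl("N", pair_a, fixed = TRUE) & !grepl("N", pair_b, fixed = TRUE)
  excluded <- sum(!usable)
  pa <- pair_a[usable]; pb <- pair_b[usable]

  Sd <- 0; Nd <- 0; blocked <- 0L; keep <- logical(length(pa))
  for (k in seq_along(pa)) {
    d <- .codon_pair_diffs(pa[k], pb[k])
    if (is.null(d)) { blocked <- blocked + 1L; next }
    keep[k] <- TRUE
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  ncod <- sum(keep)
  S <- (sum(syn[pa[keep]]) + sum(syn[pb[keep]])) / 2
  N <- 3 * ncod - S
  if (ncod == 0L) stop("no comparable codons between ", a$gene_id, " and ", b$gene_id)
  if (S == 0) stop("zero synonymous sites between ", a$gene_id, " and ", b$gene_id)
  pS <- Sd / S
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- .jc_correct(pS)
  Ka <- .jc_correct(pN)
  saturated <- is.na(Ks) && pS >= 3 / 4
  structure(list(id_a = a$gene_id, id_b = b$gene_id,
                 S = S, N = N, Sd = unname(Sd), Nd = unname(Nd),
                 pS = pS, pN = pN, Ks = Ks, Ka = Ka, mu = mu,
                 T = if (is.na(Ks)) NA_real_ else Ks / (2 * mu),
                 saturated = saturated,
                 codons_compared = ncod,
                 codons_excluded = excluded,
                 paths_blocked = blocked),
            class = "ks_estimate")
}

#' Molecular-clock divergence time from Ks
#'
#' `T = Ks / (2 mu)`: substitutions accumulate at rate `mu` on each of the
#' two lineages.
#'
#' @param ks Synonymous substitutions per synonymous site.
#' @param mu Substitution rate per site per year (default `2e-9`).
#' @return Divergence time in years.
#' @examples
#' divergence_time(0.03)  # 7.5e6 years
#' @export
divergence_time <- function(ks, mu = 2e-9) {
  stopifnot(mu > 0)
  ks / (2 * mu)
}
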