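# Forward-time generators for every input the pipeline consumes, with
# planted ground truth. Mutation follows a Jukes-Cantor model (uniform
# rates); nonallelic gene conversion is a unidirectional tract copy with
# geometric tract lengths. Selection is not modeled.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

.is_stop_codon <- function(chars3) {
  paste(chars3, collapse = "") %in% c("TAA", "TAG", "TGA")
}

# apply point mutations and conversion events to one species' gene set
.evolve_branch <- function(genes, species, mu, t, conversion_rate, tract_len) {
  n_genes <- length(genes)
  L <- length(genes[[1L]])
  n_mut <- stats::rpois(1L, mu * t * L * n_genes)
  n_conv <- if (conversion_rate > 0 && n_genes >= 2L) {
    stats::rpois(1L, conversion_rate * t * n_genes)
  } else 0L
  events <- data.frame(
    time = c(stats::runif(n_mut, 0, t), stats::runif(n_conv, 0, t)),
    type = rep(c("mutation", "conversion"), c(n_mut, n_conv)),
    stringsAsFactors = FALSE)
  events <- events[order(events$time), , drop = FALSE]
  log <- vector("list", nrow(events))
  for (k in seq_len(nrow(events))) {
    if (events$type[k] == "mutation") {
      repeat {  # stop-creating mutations are rejected and redrawn
        g <- sample.int(n_genes, 1L)
        pos <- sample.int(L, 1L)
        base <- sample(setdiff(.BASES, genes[[g]][pos]), 1L)
        cand <- genes[[g]]
        cand[pos] <- base
        ci <- (pos - 1L) %/% 3L
        if (!.is_stop_codon(cand[(ci * 3L + 1L):(ci * 3L + 3L)])) {
          genes[[g]] <- cand
          log[[k]] <- data.frame(time = events$time[k], type = "mutation",
                                 species = species, gene = g, pos = pos,
                                 donor = NA_integer_, applied = TRUE,
                                 stringsAsFactors = FALSE)
          break
        }
      }
    } else {
      acceptor <- sample.int(n_genes, 1L)
      donor <- sample(setdiff(seq_len(n_genes), acceptor), 1L)
      len <- min(L, stats::rgeom(1L, 1 / tract_len) + 1L)
      start <- sample.int(L, 1L)
      end <- min(L, start + len - 1L)
      cand <- genes[[acceptor]]
      cand[start:end] <- genes[[donor]][start:end]
      codons <- matrix(cand, nrow = 3L)
      applied <- !any(apply(codons, 2L, .is_stop_codon))
      if (applied) genes[[acceptor]] <- cand
      log[[k]] <- data.frame(time = events$time[k], type = "conversion",
                             species = species, gene = acceptor, pos = start,
                             donor = donor, applied = applied,
                             stringsAsFactors = FALSE)
    }
  }
  list(genes = genes, log = do.call(rbind, log))
}

.tandem_loci <- function(ids, contig, len, spacer = 500L) {
  starts <- (seq_along(ids) - 1L) * (len + spacer)
  gene_loci(gene_id = ids, contig = contig, start = starts,
            end = starts + len, strand = "+")
}

#' Simulate a two-species tandem gene array with known history
#'
#' An ancestral stop-free CDS is drawn uniformly over sense codons. Under
#' `duplication_mode = "ancestral"` the array of `n_genes` identical copies
#' exists at the species split and every copy then evolves independently for
#' `t_split` years in each species (optionally homogenized by gene
#' conversion); under `"post_split"` a single gene evolves per species and is
#' duplicated into `n_genes` identical copies at the present (the "very
#' recent independent duplication" scenario). Point mutations follow a
#' Jukes-Cantor model at rate `mu` per site per year; mutations creating a
#' stop codon are rejected and redrawn. Conversion events copy a random
#' tract (geometric length, mean `tract_len`) from a uniformly chosen donor
#' paralog onto an acceptor within the same species and are skipped when the
#' copy would create a stop. Loci are emitted in tandem tail-to-head order.
#'
#' @param n_genes Copies per species (>= 2).
#' @param codons Codons per gene (>= 50).
#' @param mu Mutation rate per site per year (default `2e-9`).
#' @param t_split Split time in years (default `7.5e6`).
#' @param conversion_rate Expected conversion events per gene per year
#'   (default 0).
#' @param tract_len Mean conversion tract length in bases (default 300).
#' @param duplication_mode `"ancestral"` or `"post_split"`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list: `records` and `loci` (named lists over species `"sp1"`,
#'   `"sp2"` of `coding_records` / `gene_loci`), and `truth` (list of
#'   `true_t_split`, `true_mu`, `params`, `event_log`).
#' @export
simulate_array <- function(n_genes = 30L, codons = 100L, mu = 2e-9,
                           t_split = 7.5e6, conversion_rate = 0,
                           tract_len = 300L,
                           duplication_mode = c("ancestral", "post_split"),
                           seed = 1L) {
  duplication_mode <- match.arg(duplication_mode)
  stopifnot(n_genes >= 2L, codons >= 50L, mu >= 0, t_split >= 0,
            conversion_rate >= 0, tract_len >= 3L)
  .with_seed(seed, {
    sense <- .sense_codons()
    anc <- unlist(strsplit(sample(sense, codons, replace = TRUE), ""))
    species <- c("sp1", "sp2")
    out_rec <- list(); out_loci <- list(); logs <- list()
    for (sp in species) {
      if (duplication_mode == "ancestral") {
        genes <- rep(list(anc), n_genes)
        ev <- .evolve_branch(genes, sp, mu, t_split, conversion_rate,
                             tract_len)
        genes <- ev$genes
      } else {
        ev <- .evolve_branch(list(anc), sp, mu, t_split,
                             conversion_rate = 0, tract_len)
        genes <- rep(ev$genes, n_genes)
      }
      logs[[sp]] <- ev$log
      ids <- sprintf("%s_g%02d", sp, seq_len(n_genes))
      cds <- stats::setNames(
        vapply(genes, paste, character(1), collapse = ""), ids)
      out_rec[[sp]] <- build_coding_records(cds)
      out_loci[[sp]] <- .tandem_loci(ids, paste0("ctg_", sp), 3L * codons)
    }
    event_log <- do.call(rbind, logs)
    if (!is.null(event_log)) {
      event_log <- event_log[order(event_log$species, event_log$time), ]
      rownames(event_log) <- NULL
    }
    list(records = out_rec, loci = out_loci,
         truth = list(true_t_split = t_split, true_mu = mu,
                      params = list(n_genes = n_genes, codons = codons,
                                    mu = mu, t_split = t_split,
                                    conversion_rate = conversion_rate,
                                    tract_len = tract_len,
                                    duplication_mode = duplication_mode,
                                    seed = seed),
                      event_log = event_log))
  })
}

#' Simulate a replicate-level expression matrix with planted structure
#'
#' Baseline TPM per gene is log-normal (median 10 TPM, sdlog 1);
#' tissue-enriched and group-enriched genes have their focus tissues
#' multiplied by `fold`; `not_detected` genes draw a baseline below 1 TPM;
#' unplanted (`other`) genes get a mild per-tissue log-normal profile
#' (sdlog 0.5). Replicate noise is multiplicative log-normal with standard
#' deviation `noise_sigma` on the natural-log scale.
#'
#' @param n_genes Number of genes (default 200).
#' @param tissues Tissue names, or a count (default 12).
#' @param planted Optional data frame with columns `gene_id`, `category`
#'   (`tissue_enriched`, `group_enriched`, `not_detected`, `other`), `focus`
#'   (comma-separated tissues, empty for none), `fold`. Default: 20%
#'   tissue-enriched, 10% group-enriched (pairs), 10% not-detected, the rest
#'   other, all at `fold`.
#' @param fold Planted enrichment fold (default 10).
#' @param noise_sigma Log-scale replicate noise (default 0.2).
#' @param replicates Replicates per tissue (default 3).
#' @param seed Integer seed.
#' @return A list: `samples` (genes x samples TPM matrix), `replicate_map`,
#'   `matrix` (replicate-averaged `expr_matrix`), `truth` (the planted
#'   data frame).
#' @export
simulate_expression <- function(n_genes = 200L, tissues = 12L, planted = NULL,
                                fold = 10, noise_sigma = 0.2,
                                replicates = 3L, seed = 1L) {
  if (is.numeric(tissues) && length(tissues) == 1L) {
    tissues <- sprintf("tissue%02d", seq_len(tissues))
  }
  stopifnot(length(tissues) >= 3L, fold >= 1, noise_sigma >= 0,
            replicates >= 1L)
  .with_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    if (is.null(planted)) {
      n_te <- round(0.2 * n_genes); n_ge <- round(0.1 * n_genes)
      n_nd <- round(0.1 * n_genes)
      category <- rep("other", n_genes)
      category[seq_len(n_te)] <- "tissue_enriched"
      category[n_te + seq_len(n_ge)] <- "group_enriched"
      category[n_te + n_ge + seq_len(n_nd)] <- "not_detected"
      focus <- character(n_genes)
      focus[category == "tissue_enriched"] <- sample(tissues, n_te,
                                                     replace = TRUE)
      focus[category == "group_enriched"] <- vapply(seq_len(n_ge), function(i) {
        paste(sort(sample(tissues, 2L)), collapse = ",")
      }, character(1))
      planted <- data.frame(gene_id = gene_ids, category = category,
                            focus = focus,
                            fold = ifelse(category %in%
                                          c("tissue_enriched", "group_enriched"),
                                          fold, NA_real_),
                            stringsAsFactors = FALSE)
    } else {
      stopifnot(all(c("gene_id", "category", "focus") %in% names(planted)),
                nrow(planted) == n_genes)
      bad <- setdiff(unlist(strsplit(planted$focus[planted$focus != ""], ",")),
                     tissues)
      if (length(bad)) {
        stop("planted focus references unknown tissue(s): ",
             paste(bad, collapse = ", "))
      }
      if (is.null(planted$fold)) planted$fold <- fold
      gene_ids <- planted$gene_id
    }
    profile <- matrix(0, n_genes, length(tissues),
                      dimnames = list(gene_ids, tissues))
    for (i in seq_len(n_genes)) {
      cat_i <- planted$category[i]
      if (cat_i == "not_detected") {
        profile[i, ] <- stats::runif(1L, 0.05, 0.5)
      } else if (cat_i == "other") {
        base <- stats::rlnorm(1L, log(10), 1)
        profile[i, ] <- base * stats::rlnorm(length(tissues), 0, 0.5)
      } else {
        base <- stats::rlnorm(1L, log(10), 1)
        profile[i, ] <- base
        foc <- strsplit(planted$focus[i], ",")[[1]]
        profile[i, foc] <- base * planted$fold[i]
      }
    }
    samples <- do.call(cbind, lapply(tissues, function(t) {
      reps <- vapply(seq_len(replicates), function(r) {
        profile[, t] * stats::rlnorm(n_genes, 0, noise_sigma)
      }, numeric(n_genes))
      colnames(reps) <- sprintf("%s_r%d", t, seq_len(replicates))
      reps
    }))
    rownames(samples) <- gene_ids
    replicate_map <- data.frame(
      sample = colnames(samples),
      tissue = rep(tissues, each = replicates),
      stringsAsFactors = FALSE)
    agg <- vapply(tissues, function(t) {
      cols <- replicate_map$sample[replicate_map$tissue == t]
      rowMeans(samples[, cols, drop = FALSE])
    }, numeric(n_genes))
    list(samples = samples, replicate_map = replicate_map,
         matrix = expression_matrix(agg, replicate_map),
         truth = planted)
  })
}

#' Simulate decay of a conserved noncoding element
#'
#' Deletes one contiguous block covering `decay_fraction` of the element,
#' applies point substitutions to the remainder at `point_rate`, and embeds
#' the derived sequence in random flanks. The expected coverage interval
#' implied by the deletion is `[(1 - decay_fraction) * (1 - 2 point_rate),
#' 1 - decay_fraction]` (substitutions can erode local-alignment coverage
#' slightly but never extend it).
#'
#' @param cne Nucleotide sequence of the element.
#' @param decay_fraction Fraction deleted, in `[0, 1]`.
#' @param point_rate Substitution probability per remaining base, in `[0, 1]`.
#' @param seed Integer seed.
#' @param flank Random flank length added on each side (default 100).
#' @return A list: `target` (derived sequence), `expected_coverage`
#'   (length-2 numeric interval).
#' @export
simulate_cne_decay <- function(cne, decay_fraction, point_rate = 0,
                               seed = 1L, flank = 100L) {
  stopifnot(decay_fraction >= 0, decay_fraction <= 1,
            point_rate >= 0, point_rate <= 1, nchar(cne) > 0L)
  .with_seed(seed, {
    x <- strsplit(toupper(cne), "")[[1]]
    L <- length(x)
    ndel <- round(decay_fraction * L)
    if (ndel > 0L) {
      start <- sample.int(L - ndel + 1L, 1L)
      x <- x[-(start:(start + ndel - 1L))]
    }
    if (point_rate > 0 && length(x)) {
      hit <- stats::runif(length(x)) < point_rate
      x[hit] <- vapply(x[hit], function(b) sample(setdiff(.BASES, b), 1L),
                       character(1))
    }
    target <- paste(c(sample(.BASES, flank, replace = TRUE), x,
                      sample(.BASES, flank, replace = TRUE)), collapse = "")
    list(target = target,
         expected_coverage = c(max(0, (1 - decay_fraction) *
                                      (1 - 2 * point_rate)),
                               1 - decay_fraction))
  })
}
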