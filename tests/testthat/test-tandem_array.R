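triple_array <- function(strands = c("+", "+", "+"), cds = NULL) {
  if (is.null(cds)) cds <- rep(strrep("ATGGGCTATCTT", 5), 3)
  ids <- c("k1", "k2", "k3")
  records <- build_coding_records(setNames(cds, ids))
  loci <- gene_loci(ids, "ctg1", c(0, 100, 200), c(60, 160, 260), strands)
  list(records = records, loci = loci)
}

test_that("homogenized arrays report identity 1, tail-to-head, one clade", {
  x <- triple_array()
  rep <- neighbor_identity_profile(x$records, x$loci)
  expect_equal(rep$mean_neighbor_identity, 1)
  expect_length(rep$neighbor_identities, 2)
  expect_true(rep$tail_to_head)
  expect_identical(rep$clade_sizes, 3L)
  expect_identical(rep$ordered_genes, c("k1", "k2", "k3"))
})

test_that("mixed strands break tail-to-head; clades follow CDS equality", {
  x <- triple_array(strands = c("+", "+", "-"),
                    cds = c(strrep("ATGGGCTATCTT", 5),
                            strrep("ATGGGCTATCTT", 5),
                            strrep("ATGGGCTATCTC", 5)))
  rep <- neighbor_identity_profile(x$records, x$loci)
  expect_false(rep$tail_to_head)
  expect_identical(sort(rep$clade_sizes), c(1L, 2L))
  # identical-CDS clades vs relaxed identity clades
  expect_length(identical_cds_clades(x$records), 2)
  expect_length(identical_cds_clades(x$records, mode = "identity",
                                     identity_threshold = 0.99), 1)
})

test_that("array profiling validates loci", {
  x <- triple_array()
  expect_error(neighbor_identity_profile(x$records, x$loci[1:2, ]),
               "without locus")
  loci2 <- x$loci
  loci2$contig <- c("ctg1", "ctg1", "ctg2")
  expect_error(neighbor_identity_profile(x$records, loci2),
               "multiple contigs")
  loci3 <- gene_loci(c("k1", "k2", "k3"), "ctg1", c(0, 30, 200),
                     c(60, 160, 260), "+")
  expect_warning(neighbor_identity_profile(x$records, loci3), "overlap")
})

test_that("compare_arrays runs one-way ANOVA over identity samples", {
  mk <- function(ids) structure(list(neighbor_identities = ids),
                                class = "array_report")
  same <- compare_arrays(mk(c(0.9, 0.8, 0.7)), mk(c(0.7, 0.8, 0.9)))
  expect_equal(same$F, 0)

  a <- c(1.0, 0.98, 0.99); b <- c(0.5, 0.52, 0.48)
  two <- compare_arrays(mk(a), mk(b))
  # hand computation of mean squares
  gm <- mean(c(a, b))
  ssb <- 3 * (mean(a) - gm)^2 + 3 * (mean(b) - gm)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  expect_equal(two$F, (ssb / 1) / (ssw / 4))
  expect_equal(two$df, c(1, 4))

  three <- compare_arrays(mk(a), mk(b), mk(c(0.6, 0.61, 0.66)))
  expect_equal(three$df[1], 2)

  expect_error(compare_arrays(mk(0.9), mk(a)), ">= 2 neighbor identities")
  expect_error(compare_arrays(mk(a)), "at least 2 arrays")
})

test_that("gene conversion raises within-array neighbor identity (paired seeds)", {
  nip <- function(sim) {
    neighbor_identity_profile(sim$records$sp1, sim$loci$sp1)$mean_neighbor_identity
  }
  diffs <- vapply(1:4, function(s) {
    hi <- simulate_array(n_genes = 5, codons = 60, conversion_rate = 1e-6,
                         t_split = 7.5e6, seed = s)
    lo <- simulate_array(n_genes = 5, codons = 60, conversion_rate = 0,
                         t_split = 7.5e6, seed = s)
    nip(hi) - nip(lo)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("clade Ks summary separates within and between groups", {
  sim <- simulate_array(n_genes = 2, codons = 60, t_split = 0, seed = 4)
  records <- rbind(sim$records$sp1, sim$records$sp2)
  class(records) <- c("coding_records", "data.frame")
  s <- clade_ks_summary(records, clade_a = sim$records$sp1$gene_id,
                        clade_b = sim$records$sp2$gene_id)
  expect_equal(s$within_a$mean_ks, 0)   # no time, no divergence
  expect_equal(s$between$mean_ks, 0)
  expect_equal(s$between$n_pairs, 4)

  # singleton group: within refused, between still computed
  s2 <- clade_ks_summary(records, clade_a = records$gene_id[1],
                         clade_b = records$gene_id[3:4])
  expect_null(s2$within_a)
  expect_false(is.null(s2$between))

  expect_error(clade_ks_summary(records, records$gene_id[1:2],
                                records$gene_id[2:3]), "disjoint")
})
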