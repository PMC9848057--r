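test_that("classification handles the anchor examples", {
  tiss6 <- c("skin", "stomach", "t3", "t4", "t5", "t6")
  # all below detection
  cl <- classify_genes(toy_matrix(rep(0.2, 6), tiss6))
  expect_identical(cl$category, "not_detected")

  # boundary fold: 25 vs 5 elsewhere, "at least 5-fold" read as >=
  cl <- classify_genes(toy_matrix(c(25, 5, 5, 5, 5, 5), tiss6))
  expect_identical(cl$category, "tissue_enriched")
  expect_identical(cl$focus_tissues, "skin")
  expect_equal(cl$fold, 5)

  # frozen from the exhaustive rule oracle: group on {skin, stomach}
  x <- c(skin = 40, stomach = 36, t3 = 2, t4 = 2, t5 = 1, t6 = 1)
  expect_identical(oracle_classify_one(x),
                   list(category = "group_enriched",
                        focus = c("skin", "stomach")))
  cl <- classify_genes(toy_matrix(x, names(x)))
  expect_identical(cl$category, "group_enriched")
  expect_identical(cl$focus_tissues, "skin,stomach")

  # second-highest exactly 0 -> infinite fold sentinel
  cl <- classify_genes(toy_matrix(c(8, 0, 0), c("a", "b", "c")))
  expect_identical(cl$category, "tissue_enriched")
  expect_identical(cl$fold, Inf)

  expect_error(classify_genes(toy_matrix(c(1, 2), c("a", "b"))),
               "at least 3 tissues")
})

test_that("classification agrees with the exhaustive rule oracle", {
  set.seed(11)
  tissues <- sprintf("t%02d", 1:8)
  for (rep in 1:40) {
    x <- setNames(round(rlnorm(8, log(5), 1.5), 3), tissues)
    got <- classify_genes(expression_matrix(
      matrix(x, 1, dimnames = list("g", tissues))))
    want <- oracle_classify_one(x)
    expect_identical(got$category, want$category,
                     info = paste(x, collapse = ","))
    expect_identical(got$focus_tissues, paste(want$focus, collapse = ","))
  }
})

test_that("classification is a partition, monotone in fold, scale-invariant", {
  set.seed(5)
  tissues <- sprintf("t%02d", 1:10)
  tpm <- matrix(rlnorm(60 * 10, log(8), 1.2), 60, 10,
                dimnames = list(sprintf("g%02d", 1:60), tissues))
  em <- expression_matrix(tpm)
  cl5 <- classify_genes(em, fold_threshold = 5)
  # partition
  expect_identical(sort(cl5$gene_id), sort(rownames(tpm)))
  expect_true(all(cl5$category %in%
    c("not_detected", "tissue_enriched", "group_enriched", "other")))
  # enriched classes achieve the fold
  enr <- cl5$category %in% c("tissue_enriched", "group_enriched")
  expect_true(all(cl5$fold[enr] >= 5))
  # monotonicity: raising the threshold never recruits from "other"
  cl8 <- classify_genes(em, fold_threshold = 8)
  expect_true(all(cl8$category[cl5$category == "other"] %in%
                  c("other", "not_detected")))
  # scale invariance on genes detected in all tissues
  detected <- rowSums(tpm >= 1) == ncol(tpm)
  cl_scaled <- classify_genes(expression_matrix(tpm * 7))
  expect_identical(cl_scaled$category[detected], cl5$category[detected])
  expect_identical(cl_scaled$focus_tissues[detected],
                   cl5$focus_tissues[detected])
})

test_that("skin_related_set gathers anchored genes and partner tallies", {
  classes <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    category = c("tissue_enriched", "group_enriched", "group_enriched",
                 "other", "tissue_enriched"),
    focus_tissues = c("skin", "skin,stomach", "skin,stomach", "", "brain"),
    fold = c(6, 8, 9, NA, 7), stringsAsFactors = FALSE)
  s <- skin_related_set(classes, "skin")
  expect_setequal(s$genes, c("g1", "g2", "g3"))
  expect_identical(s$partner_counts, c(stomach = 2L))
  expect_error(skin_related_set(classes, "gill", tissues = c("skin", "brain")),
               "unknown tissue")
  empty <- skin_related_set(classes[0, ], "skin")
  expect_length(empty$genes, 0)
})

test_that("differential screen applies the fold/FDR/class conjunction", {
  set.seed(21)
  genes <- sprintf("g%02d", 1:30)
  a <- matrix(rlnorm(30 * 3, log(20), 0.1), 30, 3, dimnames = list(genes, NULL))
  b <- a * rlnorm(30 * 3, 0, 0.05)
  a["g01", ] <- a["g01", ] * 8      # planted 8-fold, skin gene
  a["g02", ] <- a["g02", ] * 8      # planted but classified "other"
  classes <- data.frame(
    gene_id = genes,
    category = c("tissue_enriched", rep("other", 29)),
    focus_tissues = c("skin", rep("", 29)),
    fold = c(8, rep(NA, 29)), stringsAsFactors = FALSE)
  de <- differential_screen(a, b, classes)
  expect_true(de$passes_screen[de$gene_id == "g01"])
  expect_identical(de$direction[de$gene_id == "g01"], "up_in_A")
  # fold and P pass but class is "other" -> filtered by the conjunction
  expect_false(de$passes_screen[de$gene_id == "g02"])
  expect_true(de$adjusted_p[de$gene_id == "g02"] < 0.05)
  # BH step-up equivalence
  expect_equal(de$adjusted_p, p.adjust(de$p_value, "BH"))
  # adjusted_p >= p for the least significant gene
  expect_true(max(de$adjusted_p) >= max(de$p_value))
})

test_that("differential screen degenerate cases", {
  genes <- c("g1", "g2")
  a <- matrix(5, 2, 3, dimnames = list(genes, NULL))
  b <- matrix(5, 2, 3, dimnames = list(genes, NULL))
  classes <- data.frame(gene_id = genes, category = "other",
                        focus_tissues = "", fold = NA, stringsAsFactors = FALSE)
  de <- differential_screen(a, b, classes)
  expect_equal(de$log2_fold_change, c(0, 0))   # identical values: fold 1
  expect_equal(de$p_value, c(1, 1))            # zero variance both sides
  expect_false(any(de$passes_screen))
  expect_error(differential_screen(a[, 1, drop = FALSE], b, classes),
               "2 replicates")
})
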