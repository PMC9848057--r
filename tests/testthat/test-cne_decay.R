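mk_hits <- function(id, starts, ends, ident = 1) {
  hit_records(query_id = rep(id, length(starts)), query_start = starts,
              query_end = ends, target_id = "t", percent_identity = ident,
              score = 50)
}

test_that("coverage classification uses strict cuts", {
  # 45 of 100 covered -> decayed; full -> intact; exactly 50% -> intermediate
  r <- coverage_from_hits(c(cne1 = 100L), mk_hits("cne1", 10, 55))
  expect_equal(r$coverage, 0.45)
  expect_identical(r$status, "decayed")

  r <- coverage_from_hits(c(cne1 = 100L), mk_hits("cne1", 0, 100))
  expect_identical(r$status, "intact")

  r <- coverage_from_hits(c(cne1 = 100L), mk_hits("cne1", c(0, 20), c(30, 50)))
  expect_equal(r$merged_covered, 50L)
  expect_identical(r$status, "intermediate")   # not < 0.5, not > 0.9

  # boundary: exactly at intact_cut is NOT intact
  r <- coverage_from_hits(c(cne1 = 100L), mk_hits("cne1", 0, 90))
  expect_identical(r$status, "intermediate")
})

test_that("merging matches brute-force base marking and is monotone", {
  set.seed(17)
  for (rep in 1:20) {
    len <- sample(50:200, 1)
    n <- sample(1:8, 1)
    starts <- sample(0:(len - 2), n, replace = TRUE)
    ends <- pmin(len, starts + sample(1:60, n, replace = TRUE))
    r <- coverage_from_hits(setNames(len, "c"), mk_hits("c", starts, ends))
    expect_equal(r$merged_covered, oracle_merged_bases(starts, ends, len))
    # order invariance
    perm <- sample(n)
    r2 <- coverage_from_hits(setNames(len, "c"),
                             mk_hits("c", starts[perm], ends[perm]))
    expect_equal(r2$merged_covered, r$merged_covered)
    # splitting a hit into abutting sub-hits changes nothing
    mid <- floor((starts[1] + ends[1]) / 2)
    if (mid > starts[1] && mid < ends[1]) {
      r3 <- coverage_from_hits(setNames(len, "c"),
        mk_hits("c", c(starts[1], mid, starts[-1]),
                c(mid, ends[1], ends[-1])))
      expect_equal(r3$merged_covered, r$merged_covered)
    }
    # coverage monotone non-decreasing as hits are added
    r_fewer <- coverage_from_hits(setNames(len, "c"),
                                  mk_hits("c", starts[1], ends[1]))
    expect_lte(r_fewer$merged_covered, r$merged_covered)
  }
})

test_that("coverage_from_hits filters and validates", {
  h <- mk_hits("cne1", c(0, 50), c(50, 100), ident = c(0.95, 0.3))
  r <- coverage_from_hits(c(cne1 = 100L), h, min_identity = 0.6)
  expect_equal(r$coverage, 0.5)   # low-identity hit discarded
  # no hits at all -> coverage 0, decayed
  r0 <- coverage_from_hits(c(cne1 = 100L, cne2 = 50L), h[h$query_id == "x", ])
  expect_equal(r0$coverage, c(0, 0))
  expect_identical(r0$status, c("decayed", "decayed"))
  expect_error(coverage_from_hits(c(cne1 = 40L), mk_hits("cne1", 0, 50)),
               "exceeds declared CNE length")
  expect_error(coverage_from_hits(c(cne1 = 100L), mk_hits("zz", 0, 50)),
               "unknown CNE id")
})

test_that("local alignment finds exact, embedded, and reverse-strand CNEs", {
  set.seed(23)
  cne <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  # self-alignment always yields full coverage
  h_self <- local_align_coverage(c(c1 = cne), c(t = cne))
  expect_equal(coverage_from_hits(c(c1 = 300L), h_self)$coverage, 1)
  expect_true(any(h_self$percent_identity == 1))
  # embedded in flanks
  flank <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  h_emb <- local_align_coverage(c(c1 = cne),
                                c(t = paste0(flank, cne, flank)))
  expect_equal(coverage_from_hits(c(c1 = 300L), h_emb)$coverage, 1)
  # reverse strand flagged as minus with full coverage
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cne)))
  h_rc <- local_align_coverage(c(c1 = cne), c(t = rc))
  best <- h_rc[which.max(h_rc$score), ]
  expect_identical(best$strand, "-")
  expect_equal(coverage_from_hits(c(c1 = 300L), h_rc)$coverage, 1)
  # unrelated random target: nothing above the default threshold
  unrelated <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  h_neg <- local_align_coverage(c(c1 = cne), c(t = unrelated))
  expect_equal(nrow(h_neg), 0)
  expect_error(local_align_coverage(c(c1 = cne), c(t = cne), min_score = 0),
               "min_score")
})

test_that("decay contrast flags focal-decayed, others-intact CNEs", {
  mk_rep <- function(cov) {
    data.frame(cne_id = names(cov), cne_length = 100L,
               merged_covered = as.integer(cov * 100), coverage = cov,
               status = arrayscan:::.cne_status(cov, 0.5, 0.9),
               stringsAsFactors = FALSE)
  }
  reports <- list(
    pangolin = mk_rep(c(a = 0.40, b = 0.95, c = 0.30, d = 0.20, e = 0.45)),
    dog      = mk_rep(c(a = 0.95, b = 0.97, c = 0.95, d = 0.80, e = 0.99)),
    cattle   = mk_rep(c(a = 0.96, b = 0.95, c = 0.92, d = 0.95, e = 0.98)))
  d <- decay_contrast(reports, focal = "pangolin",
                      region_labels = c(a = "SEDC", b = "SEDC", c = "SEDC",
                                        d = "SEDC", e = "SEDC"))
  tab <- d$table
  expect_true(tab$flagged[tab$cne_id == "a"])    # 0.40 vs intact elsewhere
  expect_false(tab$flagged[tab$cne_id == "b"])   # focal 0.95: not decayed
  expect_false(tab$flagged[tab$cne_id == "d"])   # dog only 0.80: not intact
  # 4 of 5 decayed in the region
  expect_equal(d$region_decay$decayed_fraction, 0.8)

  bad <- reports
  bad$dog <- bad$dog[1:4, ]
  expect_error(decay_contrast(bad, focal = "pangolin"), "differ")
})
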