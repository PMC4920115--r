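test_that("a perfect tandem passes all four conditions", {
  h <- tandem_hits(4, 2)
  a <- tandem_assignment(4, 2)
  rep <- evaluate_regularity(h, a)
  expect_true(rep$condition1 && rep$condition2 && rep$condition3 &&
                rep$condition4)
  expect_true(rep$regular)
  expect_equal(rep$median_d, 684)
  expect_length(rep$failing_monomers, 0)
  expect_equal(estimate_period(rep, h), 4L)
})

test_that("a deleted monomer breaks condition 1", {
  h <- tandem_hits(4, 2)[-5, ]  # drop the second copy of cluster A
  h$start[-(1:4)] <- h$start[-(1:4)] - 171L
  h$end <- h$start + 171L
  a <- tandem_assignment(4, 2)
  a$labels <- a$labels[-5]
  a$cluster_sizes["A"] <- 1L
  a$supports_hor <- FALSE
  rep <- evaluate_regularity(h, a)
  expect_false(rep$condition1)
  expect_true(1 %in% rep$failing_monomers)
})

test_that("an in-place strand flip breaks condition 4 and flags inversion", {
  h <- tandem_hits(4, 3)
  h$strand[6] <- "-"
  a <- tandem_assignment(4, 3)
  rep <- evaluate_regularity(h, a)
  expect_true(rep$condition1 && rep$condition2 && rep$condition3)
  expect_false(rep$condition4)
  expect_true(6 %in% rep$failing_monomers)
  scan <- list(threshold = 0.98, assignment = a,
               idm = matrix(1, 12, 12))
  cl <- classify_read("r1", 2052L, h, scan, rep)
  expect_equal(cl$label, "irregular")
  expect_true(cl$inversion_flag)
})

test_that("condition 2 uses a closed [0.95, 1.05] band on d/median(d)", {
  mk <- function(dists) {
    # three clusters, each contributing one inter-occurrence distance
    starts <- c(0L, 50L, 100L,
                0L + dists[1], 50L + dists[2], 100L + dists[3])
    o <- order(starts)
    h <- data.frame(read_id = "r1", start = starts[o],
                    end = starts[o] + 40L, strand = "+", model_id = "m",
                    score = 40, identity = 1)
    labels <- rep(c("A", "B", "C"), 2)[o]
    sizes <- stats::setNames(c(2L, 2L, 2L), c("A", "B", "C"))
    a <- structure(list(read_id = "r1", threshold = 0.98,
                        labels = labels, cluster_sizes = sizes,
                        supports_hor = TRUE),
                   class = "cluster_assignment")
    evaluate_regularity(h, a, max_gap = 1000L)
  }
  # ratios {1.00, 1.05, 0.95} -> pass (closed interval)
  expect_true(mk(c(100L, 105L, 95L))$condition2)
  # ratio 1.06 -> fail
  expect_false(mk(c(100L, 106L, 94L))$condition2)
})

test_that("condition 3 tolerates gaps up to 5 bases and overlaps", {
  h <- tandem_hits(2, 2)
  h$end[2] <- h$end[2] - 5L  # gap of exactly 5 before monomer 3
  a <- tandem_assignment(2, 2)
  expect_true(evaluate_regularity(h, a)$condition3)
  h$end[2] <- h$end[2] - 1L  # gap 6
  rep <- evaluate_regularity(h, a)
  expect_false(rep$condition3)
  expect_true(all(c(2, 3) %in% rep$failing_monomers))
  # negative gap (tolerated overlap) passes
  h <- tandem_hits(2, 2)
  h$end[2] <- h$end[2] + 3L
  expect_true(evaluate_regularity(h, a)$condition3)
})

test_that("a 300 bp insertion between monomers breaks condition 3", {
  sp <- synthetic_read_spec(seed = 41, period_k = 4, n_units = 3,
                            read_error_rate = 0,
                            anomalies = list(list(type = "nonsat",
                                                  after_unit = 1,
                                                  length = 300)))
  out <- classify_spec(sp)
  expect_false(out$result$report$condition3)
  expect_equal(out$result$classification$label, "irregular")
  expect_false(out$result$classification$transition_flag)  # 300 < 1000
})

test_that("a stretched inter-copy distance breaks condition 2", {
  h <- tandem_hits(4, 3)
  # push the middle HOR copy out by 10% of the unit length (gap bound is
  # lifted so only the spacing condition is exercised)
  h$start[5:8] <- h$start[5:8] + 68L
  h$end <- h$start + 171L
  a <- tandem_assignment(4, 3)
  rep <- evaluate_regularity(h, a, max_gap = 1000L)
  expect_false(rep$condition2)  # 752/684 = 1.0994 > 1.05
})

test_that("period estimation follows median spacing over median span", {
  h <- tandem_hits(12, 2)
  rep <- evaluate_regularity(h, tandem_assignment(12, 2))
  expect_equal(rep$median_d, 2052)
  expect_equal(estimate_period(rep, h), 12L)
  h2 <- tandem_hits(2, 3)
  rep2 <- evaluate_regularity(h2, tandem_assignment(2, 3))
  expect_equal(estimate_period(rep2, h2), 2L)
  expect_error(estimate_period(list(median_d = NA_real_), h2),
               "multi-member")
})

test_that("a dimeric array is the minimal regular HOR", {
  sp <- synthetic_read_spec(seed = 42, period_k = 2, n_units = 4,
                            read_error_rate = 0)
  cl <- classify_spec(sp)$result$classification
  expect_equal(cl$label, "regular")
  expect_equal(cl$hor_period, 2L)
})

test_that("mutually divergent monomers classify no-HOR with monomeric flag", {
  sp <- synthetic_read_spec(seed = 43, monomeric = TRUE)
  cl <- classify_spec(sp)$result$classification
  expect_equal(cl$label, "no-HOR")
  expect_true(cl$monomeric_flag)
  expect_false(cl$inversion_flag)
})

test_that("a single HOR copy gives no-HOR (insufficient span)", {
  sp <- synthetic_read_spec(seed = 44, period_k = 12, n_units = 1,
                            read_error_rate = 0)
  cl <- classify_spec(sp)$result$classification
  expect_equal(cl$label, "no-HOR")
  expect_true(is.na(cl$hor_period))
})

test_that("monomer re-use within a unit classifies irregular", {
  # unit pattern A B A C repeated three times (D21Z1-like re-use)
  sp <- synthetic_read_spec(seed = 45, period_k = 3, n_units = 1,
                            read_error_rate = 0)
  fam <- make_monomer_family(sp)
  unit <- paste0(fam$monomers[1], fam$monomers[2], fam$monomers[1],
                 fam$monomers[3])
  read <- strrep(unit, 3)
  h <- detect_monomers(read, "reuse", c(anc = fam$ancestor))
  res <- analyze_read(read, "reuse", h,
                      pipeline_config(min_read_length = 500))
  expect_equal(res$classification$label, "irregular")
  expect_false(res$report$condition2)
  expect_false(res$classification$inversion_flag)
})

test_that("fewer than two monomers is rejected by evaluate_regularity", {
  h <- tandem_hits(2, 2)[1, ]
  expect_error(evaluate_regularity(h, tandem_assignment(2, 2)), ">= 2")
})

test_that("consensus is the column-wise majority anchored on the medoid", {
  set.seed(46)
  s <- random_seq(171)
  # three identical members
  expect_identical(horscan:::majority_consensus(rep(s, 3)), s)
  # one member carries a substitution: majority restores the original
  mut <- sub_n(s, 1)
  expect_identical(horscan:::majority_consensus(c(s, mut, s)), s)
})

test_that("regular reads emit per-cluster consensi plus a unit consensus", {
  sp <- synthetic_read_spec(seed = 47, period_k = 2, n_units = 3,
                            within_cluster_divergence = 1e-4,
                            read_error_rate = 0)
  r <- synthesize_read(sp)
  # the true family members as models give exact hit boundaries
  models <- stats::setNames(r$family$monomers, c("m1", "m2"))
  h <- detect_monomers(r$sequence, r$id, models)
  res <- analyze_read(r$sequence, r$id, h,
                      pipeline_config(min_read_length = 500))
  out <- list(read = r, result = res)
  cons <- out$result$consensus
  expect_length(cons, 3)  # clusters A, B + unit
  expect_match(names(cons)[3], "/unit$")
  expect_equal(nchar(cons[[3]]), 342)
  # zero divergence: the unit consensus is the planted unit itself
  expect_identical(unname(cons[[3]]),
                   paste0(out$read$family$monomers[1],
                          out$read$family$monomers[2]))
})

test_that("regular label implies every condition boolean", {
  for (s in 1:6) {
    sp <- synthetic_read_spec(seed = 4500 + s, period_k = sample(2:6, 1),
                              n_units = 3)
    out <- classify_spec(sp)
    if (out$result$classification$label == "regular") {
      rep <- out$result$report
      expect_true(rep$condition1 && rep$condition2 && rep$condition3 &&
                    rep$condition4)
      expect_gte(out$result$classification$hor_period, 2L)
    }
  }
})
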