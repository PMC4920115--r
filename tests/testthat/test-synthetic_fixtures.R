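test_that("generation is byte-identical for a fixed seed", {
  sp <- synthetic_read_spec(seed = 61, period_k = 4, n_units = 3)
  a <- synthesize_read(sp)
  b <- synthesize_read(sp)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$truth$intervals, b$truth$intervals)
  c <- synthesize_read(synthetic_read_spec(seed = 62, period_k = 4,
                                           n_units = 3))
  expect_false(identical(a$sequence, c$sequence))
  s1 <- simulate_reads(3, seed = 7)
  s2 <- simulate_reads(3, seed = 7)
  expect_identical(s1$reads, s2$reads)
})

test_that("family members sit in the planted identity band", {
  # k = 2, divergence 0.08: oracle identity within [0.88, 0.96]
  for (s in 1:100) {
    fam <- make_monomer_family(synthetic_read_spec(seed = 6000 + s,
                                                   period_k = 2))
    id <- dp_identity(fam$monomers[1], fam$monomers[2])
    expect_gte(id, 0.88)
    expect_lte(id, 0.96)
  }
  fam1 <- make_monomer_family(synthetic_read_spec(seed = 63, period_k = 1))
  expect_identical(fam1$monomers, fam1$ancestor)
})

test_that("infeasible divergence and bad anomalies are rejected", {
  expect_error(synthetic_read_spec(seed = 1,
                                   between_cluster_divergence = 0.4),
               "between_cluster_divergence")
  expect_error(make_monomer_family(
    synthetic_read_spec(seed = 1, monomer_length = 20L, period_k = 4,
                        between_cluster_divergence = 0.04)),
    "too small")
  expect_error(synthetic_read_spec(seed = 1, anomalies = list(
    list(type = "deletion", unit = 9, monomer = 1))), "out of range")
  expect_error(synthetic_read_spec(seed = 1, anomalies = list(
    list(type = "frobnicate"))), "unknown anomaly")
})

test_that("ground truth matches the emitted sequence by construction", {
  for (s in 1:5) {
    sp <- synthetic_read_spec(seed = 6500 + s, period_k = 5, n_units = 2,
                              read_error_rate = 0.01,
                              flanks = c(120L, 80L))
    r <- synthesize_read(sp)
    iv <- r$truth$intervals
    expect_equal(iv$start[1], 0)
    expect_equal(iv$end[nrow(iv)], nchar(r$sequence))
    expect_true(all(iv$start[-1] == iv$end[-nrow(iv)]))  # contiguous
    expect_equal(sum(iv$kind == "monomer"), 10)
  }
})

test_that("planted monomer count equals detector hit count at zero error", {
  for (s in 1:6) {
    sp <- synthetic_read_spec(seed = 6600 + s, period_k = 4,
                              n_units = sample(2:3, 1),
                              read_error_rate = 0)
    out <- classify_spec(sp)
    expect_equal(nrow(out$hits),
                 sum(out$read$truth$intervals$kind == "monomer"))
  }
})

test_that("expected labels are derived from the planted anomalies", {
  lab <- function(...) synthesize_read(
    synthetic_read_spec(...))$truth[c("expected_label",
                                      "expected_inversion",
                                      "expected_transition")]
  t1 <- lab(seed = 67)
  expect_equal(t1$expected_label, "regular")
  t2 <- lab(seed = 67, anomalies = list(list(type = "inversion", unit = 1,
                                             monomer = 2)))
  expect_equal(t2$expected_label, "irregular")
  expect_true(t2$expected_inversion)
  t3 <- lab(seed = 67, anomalies = list(list(type = "nonsat",
                                             after_unit = 2,
                                             length = 1200)))
  expect_true(t3$expected_transition)
  t4 <- lab(seed = 67, monomeric = TRUE)
  expect_equal(t4$expected_label, "no-HOR")
  t5 <- lab(seed = 67, n_units = 1)
  expect_equal(t5$expected_label, "no-HOR")
})

test_that("the whole-read reverse-complement anomaly mirrors the truth", {
  base <- synthetic_read_spec(seed = 68, read_error_rate = 0)
  flipped <- synthetic_read_spec(seed = 68, read_error_rate = 0,
                                 anomalies = list(list(type = "revcomp")))
  a <- synthesize_read(base)
  b <- synthesize_read(flipped)
  expect_identical(b$sequence, revcomp(a$sequence))
  expect_true(all(b$truth$intervals$strand[
    b$truth$intervals$kind == "monomer"] == "-"))
  expect_equal(b$truth$expected_label, "regular")
})

test_that("write_simulation emits FASTA, truth TSV and truth BED", {
  sim <- simulate_reads(4, seed = 9, period_k = 3, n_units = 2)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_simulation(sim, fa, tsv, bed)
  expect_identical(read_fasta(fa), sim$reads)
  tr <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(nrow(tr), 4)
  expect_true(all(tr$expected_label == "regular"))
  b <- read.table(bed, sep = "\t")
  expect_equal(nrow(b), 4 * 6)  # 3 monomers x 2 units per read
})
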