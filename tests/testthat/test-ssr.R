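test_that("per-motif-length minimum repeat thresholds are enforced", {
  # mono: 10 repeats in, 9 out
  expect_identical(nrow(find_perfect_ssrs(strrep("A", 10))), 1L)
  expect_identical(nrow(find_perfect_ssrs(strrep("A", 9))), 0L)
  # di: 5 in, 4 out; tri: 4 in, 3 out
  expect_identical(find_perfect_ssrs(strrep("AT", 5))$motif, "AT")
  expect_identical(nrow(find_perfect_ssrs(strrep("AT", 4))), 0L)
  l <- find_perfect_ssrs(paste0("GGC", strrep("AAT", 4), "GGC"))
  expect_identical(l$motif, "AAT")
  expect_identical(l$repeats, 4L)
  expect_identical(c(l$start, l$end), c(3L, 15L))
  # tetra/penta/hexa at 3
  expect_identical(find_perfect_ssrs(strrep("ACGT", 3))$type, "tetra")
  expect_identical(find_perfect_ssrs(strrep("ACGTT", 3))$type, "penta")
  expect_identical(find_perfect_ssrs(strrep("ACGTTT", 3))$type, "hexa")
})

test_that("tracts report once, at their primitive motif length", {
  # 12 x A: a single mono locus, not also di/tri/hexa
  l <- find_perfect_ssrs(strrep("A", 12))
  expect_identical(nrow(l), 1L)
  expect_identical(l$motif_len, 1L)
  # (AT)x6 is a di locus only (ATAT is non-primitive)
  l2 <- find_perfect_ssrs(strrep("AT", 6))
  expect_identical(l2$motif_len, 2L)
  # partial trailing unit extends the tract but not the repeat count
  l3 <- find_perfect_ssrs(paste0("G", strrep("AAT", 4), "AA", "G"))
  expect_identical(l3$repeats, 4L)
  expect_identical(l3$end - l3$start, 14L)  # 12 full + 2 partial
})

test_that("N never participates in a repeat", {
  expect_identical(nrow(find_perfect_ssrs(paste0(strrep("A", 5), "N",
                                                 strrep("A", 5)))), 0L)
  expect_identical(nrow(find_perfect_ssrs(strrep("N", 30))), 0L)
})

test_that("motif standardization is rotation/revcomp invariant and idempotent", {
  expect_identical(standardize_motif("TTA"), "AAT")
  expect_identical(standardize_motif("T"), "A")
  expect_identical(standardize_motif("AAT"), "AAT")  # fixed point
  set.seed(99)
  for (i in 1:40) {
    m <- paste(sample(ACGT, sample(1:6, 1), replace = TRUE), collapse = "")
    std <- standardize_motif(m)
    expect_identical(standardize_motif(std), std)  # idempotent
    for (r in oracle_rotations(m))
      expect_identical(standardize_motif(r), std)
    expect_identical(standardize_motif(revcomp(m)), std)
  }
  # MISA-style grouping keeps strands apart
  expect_identical(standardize_motif("T", revcomp_classes = FALSE), "T")
  expect_error(standardize_motif("ANT"), "non-ACGT")
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(2024)
  for (i in 1:60) {
    s <- random_seq(sample(100:2000, 1), at = runif(1, 0.4, 0.95))
    expect_ssr_equal_oracle(s)
  }
  # adversarial: repeat-dense, low-complexity strings
  set.seed(77)
  for (i in 1:20) {
    s <- paste(sample(c("A", "T", "AT", "AAT", "AAAT", "G"), 300,
                      replace = TRUE), collapse = "")
    expect_ssr_equal_oracle(s)
  }
})

test_that("no two reported loci with the same std_motif overlap", {
  set.seed(5150)
  for (i in 1:15) {
    s <- paste(sample(c("A", "T", "AT", "AAT"), 500, replace = TRUE),
               collapse = "")
    l <- find_perfect_ssrs(s)
    if (nrow(l) < 2) next
    for (sm in unique(l$std_motif)) {
      sub <- l[l$std_motif == sm, ]
      if (nrow(sub) < 2) next
      sub <- sub[order(sub$start), ]
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
    }
  }
})

test_that("relative abundance follows loci per kilobase exactly", {
  expect_identical(relative_abundance(17, 14472), 1.175)
  expect_identical(relative_abundance(0, 5000), 0)
  expect_identical(relative_abundance(10, 10000), 1)
  expect_error(relative_abundance(1, 0), "positive")
})

test_that("summaries reproduce type percentages from counts", {
  loci <- rbind(
    data.frame(record_id = "r1", start = 0, end = 10, type = "mono",
               motif = "A", std_motif = "A", motif_len = 1, repeats = 10),
    data.frame(record_id = "r1", start = 20, end = 32, type = "tri",
               motif = "AAT", std_motif = "AAT", motif_len = 3, repeats = 4),
    data.frame(record_id = "r2", start = 5, end = 15, type = "mono",
               motif = "T", std_motif = "A", motif_len = 1, repeats = 10))
  s <- summarize_ssrs(loci, genome_sizes = c(r1 = 10000, r2 = 20000))
  expect_identical(s$total, 3L)
  expect_identical(s$by_type$count[s$by_type$type == "mono"], 2L)
  expect_equal(s$by_type$pct[s$by_type$type == "mono"], 66.67)
  expect_identical(s$by_motif$std_motif[1], "A")
  expect_equal(s$ra$ra[s$ra$record_id == "r1"], 0.2)
  # empty input: counts zero, percentages undefined
  s0 <- summarize_ssrs(loci[0, ])
  expect_identical(s0$total, 0L)
  expect_true(all(is.na(s0$by_type$pct)))
})

test_that("planted SSRs are recovered at exact coordinates", {
  plant <- list(list(motif = "AAT", repeats = 6, host = "CR"),
                list(motif = "A", repeats = 12, host = "intergenic"),
                list(motif = "ACGT", repeats = 4, host = "rrnL"))
  sim <- simulate_mitogenome(sim_params(seed = 31, planted_ssrs = plant))
  found <- find_perfect_ssrs(sim$record)
  for (i in seq_len(nrow(sim$truth$ssrs))) {
    t <- sim$truth$ssrs[i, ]
    hit <- found[found$start == t$start & found$end == t$end, ]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$std_motif, t$std_motif)
    expect_identical(hit$repeats, t$repeats)
  }
})
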