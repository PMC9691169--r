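test_that("the benchmark scores zero against itself", {
  bm <- ancestral_arrangement()
  cmp <- compare_to_benchmark(bm, bm)
  expect_identical(cmp$rs, 0L)
  expect_true(all(cmp$per_gene$status == "kept"))
})

test_that("in-place sign flips score as inversions of exactly those genes", {
  bm <- ancestral_arrangement()
  tg <- apply_rearrangement_events(bm, list(
    list(kind = "inversion", gene = "trnC"),
    list(kind = "inversion", gene = "trnP")))$order
  cmp <- compare_to_benchmark(tg, bm)
  flagged <- cmp$per_gene[cmp$per_gene$score > 0, ]
  expect_identical(sort(flagged$gene), c("trnC", "trnP"))
  expect_true(all(flagged$status == "inverted"))
  expect_identical(cmp$rs, 2L)
})

test_that("a transposition flags the moved gene and its context, per a neighbor diff", {
  bm <- ancestral_arrangement()
  tg <- apply_rearrangement_events(bm, list(
    list(kind = "transposition", gene = "trnV", after = "trnM")))$order
  cmp <- compare_to_benchmark(tg, bm)
  # manual neighbor-table diff: predecessors in target vs benchmark
  canon <- function(o) canonicalize_order(o)
  t_ <- canon(tg); b_ <- canon(bm)
  pred <- function(o) setNames(o$genes[c(length(o$genes),
                                         seq_len(length(o$genes) - 1L))],
                               o$genes)
  pt <- pred(t_); pb <- pred(b_)
  manual <- sort(names(pt)[pt[names(pt)] != pb[names(pt)]])
  flagged <- sort(cmp$per_gene$gene[cmp$per_gene$score > 0])
  expect_identical(flagged, manual)
  expect_true("trnV" %in% flagged)
  expect_gte(cmp$rs, 1L)
})

test_that("RS is invariant under rotation and reflection of the target", {
  bm <- ancestral_arrangement()
  tg <- apply_rearrangement_events(bm, list(
    list(kind = "inversion", gene = "trnC"),
    list(kind = "transposition", gene = "trnV", after = "trnM")))$order
  rs0 <- compare_to_benchmark(tg, bm)$rs
  k <- length(tg$genes)
  for (shift in c(5, 17, 30)) {
    idx <- c((shift + 1):k, 1:shift)
    rot <- gene_order(paste(ifelse(tg$signs[idx] < 0,
                                   paste0("-", tg$genes[idx]),
                                   tg$genes[idx]), collapse = ","))
    expect_identical(compare_to_benchmark(rot, bm)$rs, rs0)
  }
  refl <- gene_order(paste(ifelse(rev(-tg$signs) < 0,
                                  paste0("-", rev(tg$genes)),
                                  rev(tg$genes)), collapse = ","))
  expect_identical(compare_to_benchmark(refl, bm)$rs, rs0)
})

test_that("extract_gene_order is stable under record rotation and reflection", {
  sim <- simulate_mitogenome(sim_params(seed = 19))
  rec <- sim$record
  want <- format(canonicalize_order(ancestral_arrangement()))
  expect_identical(format(extract_gene_order(rec)), want)
  # rotate the genome (and annotation) by 5000 bases
  n <- genome_length(rec)
  shift <- 5000L
  rot_seq <- paste0(substr(rec$sequence, shift + 1, n),
                    substr(rec$sequence, 1, shift))
  fts <- rec$features
  span <- fts$end - fts$start            # generated features never wrap
  fts$start <- (fts$start - shift) %% n
  fts$wraps_origin <- fts$start + span > n
  fts$end <- ifelse(fts$wraps_origin, fts$start + span - n, fts$start + span)
  rot <- mitogenome_record("ROT", rot_seq, fts)
  expect_identical(format(extract_gene_order(rot)), want)
  # annotate everything on the complement strand
  rc_fts <- rec$features
  rc_fts$start2 <- n - rec$features$end
  rc_fts$end <- n - rec$features$start
  rc_fts$start <- rc_fts$start2
  rc_fts$start2 <- NULL
  rc_fts$strand <- -rc_fts$strand
  refl <- mitogenome_record("REFL", revcomp(rec$sequence), rc_fts)
  expect_identical(format(extract_gene_order(refl)), want)
})

test_that("CR duplication scores one duplication point", {
  bm <- ancestral_arrangement()
  res <- apply_rearrangement_events(bm, list(
    list(kind = "cr_duplication", after = "trnE")))
  expect_true("CR2" %in% res$order$genes)
  cmp <- compare_to_benchmark(res$order, bm)
  dup <- cmp$per_gene[cmp$per_gene$gene == "CR2", ]
  expect_identical(dup$status, "duplicated")
  expect_identical(dup$score, 1L)
})

test_that("RF counts rearranged arrangements per gene and finds conserved runs", {
  bm <- ancestral_arrangement()
  same <- compare_to_benchmark(bm, bm)
  moved <- compare_to_benchmark(
    apply_rearrangement_events(bm, list(
      list(kind = "transposition", gene = "trnV", after = "trnM")))$order, bm)
  rf <- rearrangement_frequency(list(same, moved), bm)
  expect_equal(rf$rf$rf[rf$rf$gene == "trnV"], 50)
  # all-identical input: RF 0 everywhere, conserved segment = whole genome
  rf0 <- rearrangement_frequency(list(same, same), bm)
  expect_true(all(rf0$rf$rf == 0))
  expect_identical(length(rf0$conserved_segment), length(bm$genes))
  # duplicating comparisons leaves RF unchanged
  rf2 <- rearrangement_frequency(list(same, moved, same, moved), bm)
  expect_equal(rf2$rf$rf, rf$rf$rf)
  expect_true(all(rf$rf$rf >= 0 & rf$rf$rf <= 100))
})

test_that("shuffling everything outside a preserved block leaves it as the conserved segment", {
  bm <- ancestral_arrangement()
  block <- c("trnY", "COX1", "trnL2", "COX2", "trnK", "trnD", "ATP8",
             "ATP6", "COX3", "trnG")
  # the block plus its upstream neighbor travel as one unit, so the
  # block's first gene keeps its predecessor context
  unit <- c("trnC", block)
  sgn <- setNames(bm$signs, bm$genes)
  set.seed(7)
  cmps <- lapply(1:6, function(i) {
    others <- sample(setdiff(bm$genes, unit))
    genes <- append(others, unit, after = sample(length(others), 1))
    tg <- gene_order(paste(ifelse(sgn[genes] < 0, paste0("-", genes), genes),
                           collapse = ","))
    compare_to_benchmark(tg, bm)
  })
  rf <- rearrangement_frequency(cmps, bm)
  expect_identical(rf$conserved_segment, block)
})

test_that("m disjoint translocations give every moved gene a score and RS >= m", {
  bm <- ancestral_arrangement()
  movers <- c("trnV", "trnT", "trnW")
  ev <- list(list(kind = "transposition", gene = "trnV", after = "ND2"),
             list(kind = "transposition", gene = "trnT", after = "COX2"),
             list(kind = "transposition", gene = "trnW", after = "ND6"))
  cmp <- compare_to_benchmark(apply_rearrangement_events(bm, ev)$order, bm)
  sc <- setNames(cmp$per_gene$score, cmp$per_gene$gene)
  expect_true(all(sc[movers] >= 1))
  expect_gte(cmp$rs, 3L)
})

test_that("arrangement typing is exact catalog matching", {
  sim <- simulate_mitogenome(sim_params(seed = 23))
  ord <- extract_gene_order(sim$record)
  expect_identical(assign_arrangement_type(ord), "T1")
  moved <- apply_rearrangement_events(ord, list(
    list(kind = "transposition", gene = "trnV", after = "trnM")))$order
  expect_identical(assign_arrangement_type(moved), "novel")
  # user-supplied catalog entry round-trips through the TSV format
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("type\torder",
               paste0("T2\t", format(moved))), f)
  cat2 <- c(default_catalog(), read_catalog(f))
  expect_identical(assign_arrangement_type(moved, cat2), "T2")
  # rotated copy of T2 still matches (canonical-form comparison)
  k <- length(moved$genes)
  idx <- c(8:k, 1:7)
  rot <- gene_order(paste(ifelse(moved$signs[idx] < 0,
                                 paste0("-", moved$genes[idx]),
                                 moved$genes[idx]), collapse = ","))
  expect_identical(assign_arrangement_type(rot, cat2), "T2")
})

test_that("a missing anchor falls back to the smallest present gene", {
  o <- gene_order("ND2,-trnW,COX1")
  expect_message(c1 <- canonicalize_order(o), "anchoring on 'COX1'")
  expect_identical(c1$genes[1], "COX1")
})
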