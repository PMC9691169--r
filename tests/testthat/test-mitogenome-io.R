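test_that("gene name normalization maps the common synonym spellings", {
  cases <- c("tRNA-Leu(CUN)" = "trnL1", "tRNA-Leu(UUR)" = "trnL2",
             "tRNA-Ser(AGN)" = "trnS1", "tRNA-Ser(UCN)" = "trnS2",
             "nad4l" = "ND4L", "NAD1" = "ND1", "COI" = "COX1",
             "cox3" = "COX3", "12S ribosomal RNA" = "rrnS",
             "l-rRNA" = "rrnL", "A+T rich region" = "CR",
             "D-loop" = "CR", "tRNA-Ala" = "trnA", "trnl1" = "trnL1",
             "cytochrome b" = "CYTB")
  for (raw in names(cases))
    expect_identical(normalize_gene_name(raw), unname(cases[raw]), label = raw)
  expect_error(normalize_gene_name("spacer-7"), "cannot map")
  expect_error(normalize_gene_name("trnL"), "cannot map")  # ambiguous isoacceptor
  expect_error(normalize_gene_name("  "), "empty")
})

test_that("GenBank coordinates convert to 0-based half-open and back", {
  gb <- c(
    "LOCUS       TEST01 100 bp DNA circular INV",
    "FEATURES             Location/Qualifiers",
    "     source          1..100",
    "     CDS             1..30",
    "                     /gene=\"ND3\"",
    "     tRNA            complement(10..60)",
    "                     /gene=\"trnW\"",
    "     D-loop          join(90..100,1..12)",
    "                     /gene=\"CR\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 4), collapse = " ")),
    "//")
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, f)
  rec <- read_genbank(f)[[1]]
  expect_identical(rec$id, "TEST01")
  expect_identical(genome_length(rec), 100L)
  nd3 <- rec$features[rec$features$name == "ND3", ]
  expect_identical(c(nd3$start, nd3$end, nd3$strand), c(0L, 30L, 1L))
  w <- rec$features[rec$features$name == "trnW", ]
  expect_identical(c(w$start, w$end, w$strand), c(9L, 60L, -1L))
  cr <- rec$features[rec$features$name == "CR", ]
  expect_true(cr$wraps_origin)
  expect_identical(c(cr$start, cr$end), c(89L, 12L))
  # span of the wrapping feature: 11 tail + 12 head = 23
  expect_identical(nchar(extract_gene_sequence(rec, "CR")), 23L)
})

test_that("origin-spanning join over a 14472 bp record has the right span", {
  # feature join(14400..14472,1..30): 73 + 30 = 103 bases
  f <- gene_feature("CR", 14399, 30, 1L, wraps_origin = TRUE)
  expect_identical((14472L - f$start) + f$end, 103L)
})

test_that("malformed records and out-of-bounds features are rejected", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS  X 10 bp", "//"), f)
  expect_error(read_genbank(f), "ORIGIN")
  writeLines(c(
    "LOCUS       BAD01 10 bp DNA circular INV",
    "FEATURES             Location/Qualifiers",
    "     CDS             5..40",
    "                     /gene=\"ND3\"",
    "ORIGIN",
    "        1 acgtacgtac",
    "//"), f)
  expect_error(read_genbank(f), "outside sequence")
  expect_error(mitogenome_record("X", "ACGT",
                                 rbind(gene_feature("ND1", 0, 3),
                                       gene_feature("ND1", 1, 4))),
               "duplicated")
})

test_that("extract_gene_sequence honors strand and origin wrap", {
  rec <- tiny_record()
  n <- genome_length(rec)
  # +1 non-wrapping feature: identical to slice
  expect_identical(extract_gene_sequence(rec, "COX1"),
                   substr(rec$sequence, 11, 40))
  # -1 feature: reverse complement of slice
  expect_identical(extract_gene_sequence(rec, "trnW"),
                   revcomp(substr(rec$sequence, 46, 65)))
  # wrap: rotation oracle -- rotate the genome so the feature is contiguous
  rot <- paste0(substr(rec$sequence, 111, n), substr(rec$sequence, 1, 110))
  expect_identical(extract_gene_sequence(rec, "CR"), substr(rot, 1, 15))
  expect_error(extract_gene_sequence(rec, "ND5"), "no feature")
})

test_that("genbank round-trip preserves names, coordinates, strands, sequence", {
  sim <- simulate_mitogenome(sim_params(seed = 11))
  rec <- sim$record
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, f)
  back <- read_genbank(f)[[1]]
  expect_identical(back$sequence, rec$sequence)
  expect_identical(back$features[, c("name", "start", "end", "strand",
                                     "wraps_origin")],
                   rec$features[, c("name", "start", "end", "strand",
                                    "wraps_origin")])
  expect_identical(back$id, rec$id)
  expect_true(back$circular)
})

test_that("features tile the genome with no base gained or lost", {
  sim <- simulate_mitogenome(sim_params(seed = 3))
  rec <- sim$record
  n <- genome_length(rec)
  covered <- logical(n)
  for (i in seq_len(nrow(rec$features))) {
    ft <- rec$features[i, ]
    pos <- if (ft$wraps_origin) c((ft$start + 1):n, seq_len(ft$end))
           else (ft$start + 1):ft$end
    expect_false(any(covered[pos]))  # no overlap in the generated layout
    covered[pos] <- TRUE
    # extracted length matches the span
    span <- if (ft$wraps_origin) (n - ft$start) + ft$end else ft$end - ft$start
    expect_identical(nchar(extract_gene_sequence(rec, ft$name)),
                     as.integer(span))
  }
  # genes + intergenic gaps account for every base exactly once
  expect_identical(sum(covered) + sum(!covered), n)
})

test_that("feature TSV round-trips through read_feature_tsv", {
  rec <- tiny_record()
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_feature_tsv(rec, ftsv)
  write_fasta(rec, fa)
  back <- read_feature_tsv(ftsv, read_fasta(fa))[[1]]
  expect_identical(back$features[, c("name", "start", "end", "strand")],
                   rec$features[, c("name", "start", "end", "strand")])
  expect_identical(back$sequence, rec$sequence)
})

test_that("PCG codon validation accepts typical starts and truncated stops", {
  mk <- function(s) mitogenome_record("C1", paste0(s, strrep("G", 30)),
                                      gene_feature("ND3", 0, nchar(s)))
  ok <- validate_pcg_codons(mk("ATGAAATTTCCCTAA"))
  expect_true(ok$start_ok && ok$stop_ok && !ok$truncated_stop)
  tr <- validate_pcg_codons(mk("ATAAAATTTT"))  # len 10, mod 3 == 1, ends T
  expect_true(tr$start_ok && tr$stop_ok && tr$truncated_stop)
  bad <- validate_pcg_codons(mk("GTGAAATTTCCCTGA"))
  expect_false(bad$start_ok)
  expect_false(bad$stop_ok)
  # all 13 PCGs of a simulated genome pass
  rep13 <- validate_pcg_codons(simulate_mitogenome(sim_params(seed = 8))$record)
  expect_identical(nrow(rep13), 13L)
  expect_true(all(rep13$start_ok) && all(rep13$stop_ok))
})
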