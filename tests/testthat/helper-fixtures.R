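# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately implemented differently from the package code paths they
# check.

ACGT <- c("A", "C", "G", "T")

random_seq <- function(n, at = 0.6) {
  paste(sample(ACGT, n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

# -- SSR brute-force oracle --------------------------------------------
# Finds every maximal primitive perfect tandem repeat meeting its
# threshold via a zero-width lookahead regex (one candidate per start
# position) plus explicit maximality/primitivity checks, independent of
# the package's run-length scanner.

oracle_rotations <- function(s) {
  k <- nchar(s)
  vapply(seq_len(k), function(i)
    paste0(substr(s, i, k), substr(s, 1, i - 1)), character(1))
}

oracle_primitive <- function(s) {
  # a string equals one of its nontrivial rotations iff it is periodic
  !(s %in% oracle_rotations(s)[-1])
}

oracle_std_motif <- function(s) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  min(c(oracle_rotations(s), oracle_rotations(rc)))
}

ssr_oracle <- function(seq, min_repeats = c(10L, 5L, 4L, 3L, 3L, 3L)) {
  n <- nchar(seq)
  x <- strsplit(seq, "")[[1]]
  rows <- list()
  for (m in 1:6) {
    thr <- min_repeats[m]
    pat <- sprintf("(?=(([ACGT]{%d})\\2{%d,}))", m, thr - 1L)
    mt <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (mt[1] == -1L) next
    cs <- attr(mt, "capture.start")
    cl <- attr(mt, "capture.length")
    for (k in seq_along(mt)) {
      s <- cs[k, 1L]
      tl <- cl[k, 1L]
      motif <- substr(seq, s, s + m - 1L)
      if (!oracle_primitive(motif)) next
      # left-maximality: previous base must not extend the tract
      if (s > 1L && x[s - 1L] %in% ACGT && x[s - 1L] == x[s - 1L + m]) next
      # extend right over a partial trailing unit
      e <- s + tl - 1L
      while (e < n && x[e + 1L] %in% ACGT && x[e + 1L] == x[e + 1L - m])
        e <- e + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        start = s - 1L, end = e, motif = motif,
        std_motif = oracle_std_motif(motif),
        motif_len = m, repeats = tl %/% m, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), std_motif = character(0),
                      motif_len = integer(0), repeats = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$motif_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

expect_ssr_equal_oracle <- function(seq) {
  got <- find_perfect_ssrs(seq)
  want <- ssr_oracle(seq)
  cols <- c("start", "end", "motif", "std_motif", "motif_len", "repeats")
  got <- got[, cols]
  rownames(got) <- NULL
  expect_equal(got, want[, cols])
}

# -- motif brute-force oracle ------------------------------------------
# plain per-window, per-position comparison on the linearized sequence
# (both strands), no circular wrap
motif_oracle <- function(seq, pattern_text, max_mismatch) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"), N = ACGT)
  pat <- iupac[strsplit(toupper(pattern_text), "")[[1]]]
  L <- length(pat)
  one_strand <- function(s, strand) {
    x <- strsplit(s, "")[[1]]
    n <- length(x)
    hits <- list()
    for (i in seq_len(n - L + 1L)) {
      mm <- sum(vapply(seq_len(L), function(j)
        !(x[i + j - 1L] %in% pat[[j]]), logical(1)))
      if (mm <= max_mismatch) {
        start0 <- if (strand == 1L) i - 1L else n - (i - 1L) - L
        hits[[length(hits) + 1L]] <- data.frame(start = start0,
                                                strand = strand,
                                                mismatches = mm)
      }
    }
    if (length(hits) == 0L) NULL else do.call(rbind, hits)
  }
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  out <- rbind(one_strand(seq, 1L), one_strand(rc, -1L))
  if (is.null(out))
    return(data.frame(start = integer(0), strand = integer(0),
                      mismatches = integer(0)))
  out <- out[order(out$start, -out$strand), ]
  rownames(out) <- NULL
  out
}

# -- published species-complex distance matrices -----------------------
iovatus_matrices <- function() {
  list(rrnL = read_distance_tsv(system.file("extdata", "iovatus_rrnL_k2p.tsv",
                                            package = "mitotick")),
       COX1 = read_distance_tsv(system.file("extdata", "iovatus_COX1_k2p.tsv",
                                            package = "mitotick")))
}

iacutitarsus_matrices <- function() {
  list(rrnL = read_distance_tsv(system.file("extdata",
                                            "iacutitarsus_rrnL_k2p.tsv",
                                            package = "mitotick")),
       COX1 = read_distance_tsv(system.file("extdata",
                                            "iacutitarsus_COX1_k2p.tsv",
                                            package = "mitotick")))
}

# small hand-built annotated record on a fixed 120 bp sequence
tiny_record <- function() {
  seq <- strrep("ACGTTGCAAT", 12)
  feats <- rbind(
    gene_feature("COX1", 10, 40, 1L),
    gene_feature("trnW", 45, 65, -1L),
    gene_feature("CR", 110, 5, 1L, wraps_origin = TRUE))
  mitogenome_record("TINY1", seq, feats, organism = "Testus tickus")
}
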