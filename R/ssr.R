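# Perfect microsatellite (SSR) mining. A locus is a maximal perfect tandem
# repeat of a primitive 1-6 bp motif whose whole-unit repeat count meets
# the per-motif-length minimum (Krait/MISA-style thresholds). Motif classes
# group cyclic rotations and, by default, reverse complements.

.SSR_TYPES <- c("mono", "di", "tri", "tetra", "penta", "hexa")

#' SSR scan configuration
#'
#' Default minimum whole-unit repeat counts: 10 (mono), 5 (di), 4 (tri),
#' 3 (tetra), 3 (penta), 3 (hexa).
#'
#' @param min_repeats integer vector of length 6, minimum repeats for motif
#'   lengths 1..6.
#' @param revcomp_classes logical; if TRUE (default) motif standardization
#'   groups reverse complements (Krait-style); FALSE keeps strand-specific
#'   classes (MISA-style).
#' @return object of class `ssr_config`.
#' @export
ssr_config <- function(min_repeats = c(10L, 5L, 4L, 3L, 3L, 3L),
                       revcomp_classes = TRUE) {
  min_repeats <- as.integer(min_repeats)
  stopifnot(length(min_repeats) == 6L, all(min_repeats >= 2L))
  structure(list(min_repeats = min_repeats,
                 max_motif_len = 6L,
                 revcomp_classes = isTRUE(revcomp_classes)),
            class = "ssr_config")
}

.is_primitive <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(TRUE)
  for (d in seq_len(m - 1L)) {
    if (m %% d != 0L) next
    if (strrep(substr(motif, 1L, d), m %/% d) == motif) return(FALSE)
  }
  TRUE
}

.rotations <- function(motif) {
  m <- nchar(motif)
  dd <- paste0(motif, motif)
  vapply(seq_len(m), function(k) substr(dd, k, k + m - 1L), character(1))
}

#' Standardize a microsatellite motif to its class representative
#'
#' Returns the lexicographically smallest string among all cyclic rotations
#' of the motif and (by default) all cyclic rotations of its reverse
#' complement, so e.g. "TTA", "TAT" and "ATT" all map to "AAT". Idempotent.
#'
#' @param motif primitive repeat unit over A/C/G/T, length 1-6.
#' @param revcomp_classes group reverse complements (default TRUE).
#' @return character scalar, the standardized motif.
#' @export
#' @examples
#' standardize_motif("TTA")  # "AAT"
#' standardize_motif("T")    # "A"
standardize_motif <- function(motif, revcomp_classes = TRUE) {
  stopifnot(is.character(motif), length(motif) == 1L)
  motif <- toupper(motif)
  if (nchar(motif) < 1L || nchar(motif) > 6L)
    stop("motif length must be 1-6", call. = FALSE)
  if (!all(.chars(motif) %in% .ACGT))
    stop(sprintf("motif '%s' contains non-ACGT characters", motif),
         call. = FALSE)
  cand <- .rotations(motif)
  if (revcomp_classes) cand <- c(cand, .rotations(revcomp(motif)))
  min(cand)
}

.empty_ssr_df <- function() {
  data.frame(record_id = character(0), start = integer(0), end = integer(0),
             type = character(0), motif = character(0),
             std_motif = character(0), motif_len = integer(0),
             repeats = integer(0), stringsAsFactors = FALSE)
}

#' Find perfect microsatellites in a sequence
#'
#' Reports every maximal perfect tandem tract whose primitive repeat unit
#' (1-6 bp) occurs at least the configured number of whole times. A tract
#' is reported once, at its primitive motif length; a partial trailing unit
#' is included in the tract span (`end - start`) but does not increment
#' `repeats`. N and other ambiguity characters never participate in a
#' repeat. Sequences are scanned linearly (no origin wrap-around), matching
#' standard SSR tools on deposited records.
#'
#' @param seq nucleotide character scalar (or a `mitogenome`).
#' @param config an [ssr_config()].
#' @param record_id id used in the output (taken from the record if one is
#'   given).
#' @return data.frame with columns record_id, start, end (0-based
#'   half-open), type, motif, std_motif, motif_len, repeats; sorted by
#'   start then motif_len.
#' @export
find_perfect_ssrs <- function(seq, config = ssr_config(), record_id = NA_character_) {
  if (inherits(seq, "mitogenome")) {
    if (is.na(record_id)) record_id <- seq$id
    seq <- seq$sequence
  }
  s <- .clean_seq(seq)
  n <- nchar(s)
  out <- .empty_ssr_df()
  if (n == 0L) return(out)
  x <- .chars(s)
  valid <- x %in% .ACGT
  rows <- list()
  for (m in seq_len(config$max_motif_len)) {
    if (n < m * 2L) next
    idx <- seq_len(n - m)
    eq <- (x[idx] == x[idx + m]) & valid[idx] & valid[idx + m]
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (j in which(r$values)) {
      run_start <- pos[j]            # 1-based index into eq / sequence
      run_len <- r$lengths[j]
      tract_len <- run_len + m
      reps <- tract_len %/% m
      if (reps < config$min_repeats[m]) next
      motif <- substr(s, run_start, run_start + m - 1L)
      if (!.is_primitive(motif)) next
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = record_id,
        start = run_start - 1L,               # 0-based
        end = run_start - 1L + tract_len,     # half-open, incl. partial unit
        type = .SSR_TYPES[m], motif = motif,
        std_motif = standardize_motif(motif, config$revcomp_classes),
        motif_len = m, repeats = reps, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(out)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$start, out$motif_len), , drop = FALSE]
}

#' Relative abundance of microsatellites
#'
#' RA = loci / genome size x 1000, i.e. loci per kilobase; reported to
#' 3 decimals.
#'
#' @param n_loci number of microsatellite loci.
#' @param genome_size genome length in bases (> 0).
#' @return numeric scalar.
#' @export
#' @examples
#' relative_abundance(17, 14472)  # 1.175
relative_abundance <- function(n_loci, genome_size) {
  if (genome_size <= 0) stop("genome_size must be positive", call. = FALSE)
  round(n_loci / genome_size * 1000, 3)
}

#' Summarize microsatellite loci by type and motif class
#'
#' @param loci data.frame of loci (output of [find_perfect_ssrs()], possibly
#'   rbind-ed across records).
#' @param genome_sizes optional named numeric vector record_id -> genome
#'   size; when supplied, per-record relative abundances are included.
#' @return list with `total`, `by_type` (count + percentage, 2 decimals),
#'   `by_motif` (counts per std_motif, decreasing), and optionally `ra`.
#' @export
summarize_ssrs <- function(loci, genome_sizes = NULL) {
  total <- nrow(loci)
  by_type <- data.frame(type = .SSR_TYPES,
                        count = vapply(.SSR_TYPES, function(t)
                          sum(loci$type == t), integer(1)),
                        stringsAsFactors = FALSE, row.names = NULL)
  by_type$pct <- if (total > 0L) round(100 * by_type$count / total, 2)
                 else NA_real_
  by_motif <- if (total > 0L) {
    tab <- sort(table(loci$std_motif), decreasing = TRUE)
    data.frame(std_motif = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  } else data.frame(std_motif = character(0), count = integer(0))
  out <- list(total = total, by_type = by_type, by_motif = by_motif)
  if (!is.null(genome_sizes)) {
    ids <- names(genome_sizes)
    out$ra <- data.frame(
      record_id = ids,
      n_loci = vapply(ids, function(i) sum(loci$record_id == i), integer(1)),
      genome_size = as.numeric(genome_sizes), stringsAsFactors = FALSE,
      row.names = NULL)
    out$ra$ra <- mapply(relative_abundance, out$ra$n_loci, out$ra$genome_size)
  }
  out
}
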