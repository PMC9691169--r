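# IUPAC degenerate motif scanning. The default pattern is the 17 bp
# Tick-Box consensus found at fixed positions of tick mitogenomes
# (downstream of ND1 and near the 3' end of rrnL / within trnL1).

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Parse an IUPAC degenerate pattern
#'
#' @param pattern character scalar over the IUPAC nucleotide alphabet
#'   (case-insensitive).
#' @return object of class `motif_pattern`: list(pattern, length, allowed)
#'   where allowed is a per-position list of admissible bases.
#' @export
#' @examples
#' parse_iupac("TTGyrTChwwwTwwGdA")$length  # 17
parse_iupac <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (!nzchar(pattern)) stop("empty pattern", call. = FALSE)
  up <- toupper(pattern)
  ch <- .chars(up)
  bad <- which(!ch %in% names(.IUPAC_SETS))
  if (length(bad) > 0L)
    stop(sprintf("invalid IUPAC code '%s' at position %d",
                 .chars(pattern)[bad[1]], bad[1]), call. = FALSE)
  structure(list(pattern = pattern, length = length(ch),
                 allowed = .IUPAC_SETS[ch]),
            class = "motif_pattern")
}

#' The Tick-Box degenerate consensus pattern
#'
#' 17 bp degenerate consensus 5'-TTGyrTChwwwTwwGdA-3' described for tick
#' mitochondrial genomes.
#'
#' @return a `motif_pattern`.
#' @export
tick_box_pattern <- function() parse_iupac("TTGyrTChwwwTwwGdA")

# mismatch count of every window of `s` (chars vector, possibly extended
# for circular wrap) against the pattern; returns integer vector over
# window starts 1..nw
.window_mismatches <- function(ch, nw, pat) {
  mm <- integer(nw)
  base <- seq_len(nw)
  for (j in seq_len(pat$length)) {
    mm <- mm + !(ch[base + j - 1L] %in% pat$allowed[[j]])
  }
  mm
}

#' Scan a sequence or record for a degenerate motif on both strands
#'
#' Every window with at most `max_mismatch` positions outside the allowed
#' base set is reported. Light-strand hits carry strand -1 with
#' heavy-strand coordinates; `match` and mismatch positions are given
#' 5'->3' on the hit's own strand. On circular records windows crossing
#' the origin are scanned too (their `end` exceeds the genome length and
#' wraps).
#'
#' @param record a `mitogenome` or a plain sequence string.
#' @param pattern a `motif_pattern` (default the Tick-Box consensus).
#' @param max_mismatch mismatch tolerance (default 1: the known
#'   I. vespertilionis occurrence deviates from the printed consensus at
#'   one degenerate position).
#' @param circular scan across the origin (default: record's flag, TRUE
#'   for plain sequences).
#' @return data.frame: record_id, start, end (0-based half-open; end may
#'   exceed the genome length for wrapping hits), strand, match,
#'   mismatches, mismatch_positions (comma-separated, 1-based in the
#'   pattern).
#' @export
scan_motif <- function(record, pattern = tick_box_pattern(),
                       max_mismatch = 1L, circular = NULL) {
  if (inherits(record, "mitogenome")) {
    seqs <- record$sequence; rid <- record$id
    circular <- circular %||% record$circular
  } else {
    seqs <- .clean_seq(record); rid <- NA_character_
    circular <- circular %||% TRUE
  }
  n <- nchar(seqs)
  L <- pattern$length
  if (n < L) stop("sequence shorter than pattern", call. = FALSE)

  scan_one <- function(s, strand) {
    ext <- if (circular) paste0(s, substr(s, 1L, L - 1L)) else s
    ch <- .chars(ext)
    nw <- if (circular) n else n - L + 1L
    mm <- .window_mismatches(ch, nw, pattern)
    hit_i <- which(mm <= max_mismatch)
    if (length(hit_i) == 0L) return(NULL)
    do.call(rbind, lapply(hit_i, function(i) {
      win <- substr(ext, i, i + L - 1L)
      wch <- .chars(win)
      mpos <- which(vapply(seq_len(L), function(j)
        !(wch[j] %in% pattern$allowed[[j]]), logical(1)))
      start0 <- if (strand == 1L) i - 1L else (n - (i - 1L) - L) %% n
      data.frame(record_id = rid, start = start0, end = start0 + L,
                 strand = strand, match = win, mismatches = mm[i],
                 mismatch_positions = paste(mpos, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }
  fwd <- scan_one(seqs, 1L)
  rev <- scan_one(revcomp(seqs), -1L)
  out <- rbind(fwd, rev)
  if (is.null(out))
    return(data.frame(record_id = character(0), start = integer(0),
                      end = integer(0), strand = integer(0),
                      match = character(0), mismatches = integer(0),
                      mismatch_positions = character(0),
                      stringsAsFactors = FALSE))
  out <- out[order(out$start, -out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate motif hits with genomic context
#'
#' A hit fully inside a feature is labelled "within <gene>" (the smallest
#' containing feature wins); otherwise, if its 5' start lies within
#' `downstream_window` bases 3' of a gene (strand-aware), it is labelled
#' "downstream of <gene>"; otherwise "intergenic".
#'
#' @param hits data.frame from [scan_motif()].
#' @param record the annotated `mitogenome` the hits came from.
#' @param downstream_window bases counted as "downstream" (default 100).
#' @return `hits` with an added `context` column.
#' @export
annotate_hits <- function(hits, record, downstream_window = 100L) {
  n <- genome_length(record)
  fts <- record$features
  span <- .feature_span(fts, n)
  hits$context <- vapply(seq_len(nrow(hits)), function(i) {
    s <- hits$start[i]; L <- hits$end[i] - hits$start[i]
    # containment: rotate so the feature starts at 0
    rel <- (s - fts$start) %% n
    inside <- which(rel + L <= span)
    if (length(inside) > 0L) {
      f <- inside[which.min(span[inside])]
      return(paste("within", fts$name[f]))
    }
    # downstream: distance from each gene's 3' end to the hit's 5' start;
    # genes transcribed on the hit's own strand take precedence (a motif
    # downstream of a gene reads in that gene's transcription direction)
    off <- ifelse(fts$strand == 1L,
                  (s - fts$end) %% n,
                  (fts$start - (s + L)) %% n)
    cand <- which(off < downstream_window)
    if (length(cand) > 0L) {
      same <- cand[fts$strand[cand] == hits$strand[i]]
      pool <- if (length(same) > 0L) same else cand
      f <- pool[which.min(off[pool])]
      return(paste("downstream of", fts$name[f]))
    }
    "intergenic"
  }, character(1))
  hits
}
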