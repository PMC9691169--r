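# Nucleotide composition and strand-skew statistics.
# AT-skew = (A - T)/(A + T), GC-skew = (G - C)/(G + C), computed on counts;
# a zero denominator propagates NA (undefined), never 0.

#' Base composition and skew statistics of a sequence
#'
#' Counts are case-insensitive; IUPAC ambiguity characters are tallied as
#' "other" and excluded from the skew denominators.
#'
#' @param seq nucleotide character scalar (non-empty).
#' @return object of class `composition_stats`: a one-row data.frame with
#'   columns length, A, C, G, T, other, pct_A, pct_C, pct_G, pct_T,
#'   pct_AT, pct_GC, at_skew, gc_skew. Percentages and skews are kept at
#'   full precision; round for display.
#' @export
#' @examples
#' base_composition("AAAT")$at_skew  # (3-1)/(3+1) = 0.5
base_composition <- function(seq) {
  s <- .clean_seq(seq)
  if (nchar(s) == 0L) stop("empty sequence", call. = FALSE)
  ch <- .chars(s)
  n <- length(ch)
  cnt <- vapply(.ACGT, function(b) sum(ch == b), integer(1))
  other <- n - sum(cnt)
  a <- cnt[["A"]]; c_ <- cnt[["C"]]; g <- cnt[["G"]]; t <- cnt[["T"]]
  sk <- function(num, den) if (den == 0L) NA_real_ else num / den
  out <- data.frame(
    length = n, A = a, C = c_, G = g, T = t, other = other,
    pct_A = 100 * a / n, pct_C = 100 * c_ / n,
    pct_G = 100 * g / n, pct_T = 100 * t / n,
    pct_AT = 100 * (a + t) / n, pct_GC = 100 * (g + c_) / n,
    at_skew = sk(a - t, a + t), gc_skew = sk(g - c_, g + c_))
  class(out) <- c("composition_stats", class(out))
  out
}

#' AT- and GC-skew of a sequence
#'
#' @param seq nucleotide character scalar.
#' @return named numeric vector `c(at_skew, gc_skew)`; NA where the
#'   denominator is zero.
#' @export
skew <- function(seq) {
  cs <- base_composition(seq)
  c(at_skew = cs$at_skew, gc_skew = cs$gc_skew)
}

.table_regions <- function() c("genome", .PCGS, "rrnL", "rrnS", "CR")

#' Composition table per genome and per gene/region
#'
#' One row per record for the whole genome, each of the 13 PCGs, the two
#' rRNAs and the control region. Gene rows are computed on the coding
#' orientation (light-strand genes reverse-complemented) by default, which
#' makes the systematically higher GC-skew of light-chain genes visible as
#' a strand-orientation effect; `gene_strand = "heavy"` uses the printed
#' strand instead. Missing genes yield NA rows.
#'
#' @param records list of `mitogenome` records.
#' @param gene_strand "coding" (default) or "heavy".
#' @return data.frame with columns record_id, region, length, A, C, G, T,
#'   other, pct_AT, pct_GC, at_skew, gc_skew (percentages rounded to 2,
#'   skews to 3 decimals, matching reporting style; use
#'   [base_composition()] for full precision).
#' @export
genome_gene_table <- function(records, gene_strand = c("coding", "heavy")) {
  gene_strand <- match.arg(gene_strand)
  if (inherits(records, "mitogenome")) records <- list(records)
  rows <- list()
  for (rec in records) {
    for (region in .table_regions()) {
      s <- if (region == "genome") rec$sequence
      else if (region %in% rec$features$name) {
        if (gene_strand == "coding") extract_gene_sequence(rec, region)
        else {
          f <- rec$features[rec$features$name == region, ][1, ]
          n <- genome_length(rec)
          if (f$wraps_origin)
            paste0(substr(rec$sequence, f$start + 1L, n),
                   substr(rec$sequence, 1L, f$end))
          else substr(rec$sequence, f$start + 1L, f$end)
        }
      } else NA_character_
      if (is.na(s)) {
        message(sprintf("record %s: region %s missing, emitting NA row",
                        rec$id, region))
        rows[[length(rows) + 1L]] <- data.frame(
          record_id = rec$id, region = region, length = NA_integer_,
          A = NA_integer_, C = NA_integer_, G = NA_integer_, T = NA_integer_,
          other = NA_integer_, pct_AT = NA_real_, pct_GC = NA_real_,
          at_skew = NA_real_, gc_skew = NA_real_, stringsAsFactors = FALSE)
      } else {
        cs <- base_composition(s)
        rows[[length(rows) + 1L]] <- data.frame(
          record_id = rec$id, region = region, length = cs$length,
          A = cs$A, C = cs$C, G = cs$G, T = cs$T, other = cs$other,
          pct_AT = round(cs$pct_AT, 2), pct_GC = round(cs$pct_GC, 2),
          at_skew = round(cs$at_skew, 3), gc_skew = round(cs$gc_skew, 3),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-genus aggregates of composition statistics
#'
#' @param tbl output of [genome_gene_table()].
#' @param genus named character vector mapping record_id -> genus.
#' @param region which region's rows to aggregate (default "genome").
#' @return data.frame with one row per genus: n, mean/min/max of pct_AT,
#'   at_skew, gc_skew.
#' @export
composition_aggregates <- function(tbl, genus, region = "genome") {
  sub <- tbl[tbl$region == region & tbl$record_id %in% names(genus), ]
  if (nrow(sub) == 0L) stop("no rows to aggregate", call. = FALSE)
  sub$genus <- genus[sub$record_id]
  agg <- lapply(split(sub, sub$genus), function(d) {
    f <- function(x, fun) fun(x, na.rm = TRUE)
    data.frame(genus = d$genus[1], n = nrow(d),
               mean_pct_AT = f(d$pct_AT, mean), min_pct_AT = f(d$pct_AT, min),
               max_pct_AT = f(d$pct_AT, max),
               mean_at_skew = f(d$at_skew, mean), min_at_skew = f(d$at_skew, min),
               max_at_skew = f(d$at_skew, max),
               mean_gc_skew = f(d$gc_skew, mean), min_gc_skew = f(d$gc_skew, min),
               max_gc_skew = f(d$gc_skew, max),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(agg, list(make.row.names = FALSE)))
}
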