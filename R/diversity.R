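# Variable-site statistics, nucleotide diversity (pi), sliding-window pi,
# and concatenation of per-gene alignments into a partitioned supermatrix.
# Windows are indexed by alignment columns (DnaSP convention), and gap or
# ambiguous positions are dropped pair by pair, consistent with the
# distance module.

#' Variable-site count and percentage of an alignment
#'
#' A column is variable iff at least two distinct unambiguous bases occur
#' among its non-gap characters. The percentage denominator is the number
#' of columns with at least two usable (A/C/G/T) characters, which is
#' robust to ragged alignment ends.
#'
#' @param alignment named character vector / `DNAStringSet` / character
#'   matrix; at least 2 sequences of equal length.
#' @return list(count, considered, percent).
#' @export
variable_sites <- function(alignment) {
  m <- .as_aln_matrix(alignment)
  usable <- matrix(m %in% .ACGT, nrow = nrow(m))
  n_usable <- colSums(usable)
  considered <- sum(n_usable >= 2L)
  var_col <- vapply(seq_len(ncol(m)), function(j) {
    b <- m[usable[, j], j]
    length(unique(b)) >= 2L
  }, logical(1))
  count <- sum(var_col)
  list(count = count, considered = considered,
       percent = if (considered > 0L) 100 * count / considered else NA_real_)
}

# per-pair (differences, usable) over a column subset
.pi_of <- function(m, cols = seq_len(ncol(m))) {
  k <- nrow(m)
  vals <- c()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    a <- m[i, cols]; b <- m[j, cols]
    ok <- (a %in% .ACGT) & (b %in% .ACGT)
    L <- sum(ok)
    if (L == 0L) next  # pair skipped
    vals <- c(vals, sum(a[ok] != b[ok]) / L)
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Nucleotide diversity (pi) of an alignment
#'
#' Mean over all unordered sequence pairs of per-site differences with
#' pairwise deletion of gap/ambiguous positions. Pairs with zero usable
#' sites are skipped.
#'
#' @inheritParams variable_sites
#' @return numeric scalar pi in [0, 1].
#' @export
nucleotide_diversity <- function(alignment) {
  m <- .as_aln_matrix(alignment)
  .pi_of(m)
}

#' Sliding-window nucleotide diversity
#'
#' Windows of `window` alignment columns advancing by `step` from column 0;
#' a trailing partial window is dropped, so the number of windows is
#' floor((ncol - window)/step) + 1.
#'
#' @inheritParams variable_sites
#' @param window window size in columns (default 200).
#' @param step step size in columns (default 20).
#' @return data.frame with columns start (0-based column), mid, pi.
#' @export
sliding_window_pi <- function(alignment, window = 200L, step = 20L) {
  m <- .as_aln_matrix(alignment)
  nc <- ncol(m)
  if (window > nc) stop("window exceeds alignment length", call. = FALSE)
  starts0 <- seq(0L, nc - window, by = step)
  pi <- vapply(starts0, function(s0)
    .pi_of(m, (s0 + 1L):(s0 + window)), numeric(1))
  data.frame(start = starts0, mid = starts0 + window / 2, pi = pi)
}

#' Concatenate per-gene alignments into a partitioned supermatrix
#'
#' Taxa are matched by id across genes; a taxon absent from a gene gets
#' all-gap filler for that partition. Partition boundaries are 1-based
#' inclusive.
#'
#' @param alignments named list of alignments (names = gene/partition
#'   names), each a named character vector (or `DNAStringSet`).
#' @return object of class `supermatrix`: list(alignment = named character
#'   vector, partitions = data.frame(gene, start, end)).
#' @export
concatenate_alignments <- function(alignments) {
  stopifnot(is.list(alignments), length(alignments) >= 1L)
  if (is.null(names(alignments)))
    names(alignments) <- paste0("gene", seq_along(alignments))
  alignments <- lapply(alignments, function(a) {
    if (methods::is(a, "XStringSet"))
      a <- stats::setNames(as.character(a), names(a))
    if (anyDuplicated(names(a)))
      stop("duplicate taxon id within one gene alignment", call. = FALSE)
    if (length(unique(nchar(a))) != 1L)
      stop("ragged alignment", call. = FALSE)
    toupper(a)
  })
  taxa <- unique(unlist(lapply(alignments, names)))
  lens <- vapply(alignments, function(a) nchar(a[[1]]), integer(1))
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  concat <- vapply(taxa, function(tx) {
    paste(vapply(seq_along(alignments), function(g) {
      a <- alignments[[g]]
      if (tx %in% names(a)) a[[tx]] else strrep("-", lens[g])
    }, character(1)), collapse = "")
  }, character(1))
  structure(list(alignment = concat,
                 partitions = data.frame(gene = names(alignments),
                                         start = starts, end = ends,
                                         stringsAsFactors = FALSE,
                                         row.names = NULL)),
            class = "supermatrix")
}

#' Write supermatrix partition definitions
#'
#' @param sm a `supermatrix`.
#' @param path output path.
#' @param format "raxml" (`DNA, gene = start-end`) or "nexus"
#'   (a `sets` block with charset lines).
#' @return invisibly, `path`.
#' @export
write_partitions <- function(sm, path, format = c("raxml", "nexus")) {
  format <- match.arg(format)
  p <- sm$partitions
  lines <- if (format == "raxml") {
    sprintf("DNA, %s = %d-%d", p$gene, p$start, p$end)
  } else {
    c("#nexus", "begin sets;",
      sprintf("  charset %s = %d-%d;", p$gene, p$start, p$end),
      "end;")
  }
  writeLines(lines, path)
  invisible(path)
}
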