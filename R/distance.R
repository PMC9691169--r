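# Kimura 2-parameter distances on aligned sequences and threshold-based
# species-complex delimitation. Transitions are A<->G and C<->T; all other
# substitutions are transversions. Sites where either sequence carries a
# gap or ambiguity are dropped pair by pair (pairwise deletion).

# site counts for one aligned pair
.pair_counts <- function(a, b) {
  usable <- (a %in% .ACGT) & (b %in% .ACGT)
  a <- a[usable]; b <- b[usable]
  diff <- a != b
  ts <- sum((a == "A" & b == "G") | (a == "G" & b == "A") |
            (a == "C" & b == "T") | (a == "T" & b == "C"))
  list(L = length(a), ts = ts, tv = sum(diff) - ts)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' With P and Q the transition and transversion proportions over usable
#' sites, d = -(1/2) ln((1 - 2P - Q) sqrt(1 - 2Q)). When the log argument
#' is non-positive the distance is undefined and NA is returned (flagged,
#' not an error).
#'
#' @param a,b equal-length aligned sequences (characters or single strings;
#'   gaps "-" and ambiguity codes are excluded pairwise).
#' @return numeric distance, or NA if undefined.
#' @export
#' @examples
#' k2p_distance(strrep("A", 90), strrep("A", 90))  # 0
k2p_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- .chars(toupper(a))
  if (is.character(b) && length(b) == 1L) b <- .chars(toupper(b))
  if (length(a) != length(b))
    stop("aligned sequences must have equal length", call. = FALSE)
  cnt <- .pair_counts(a, b)
  if (cnt$L == 0L) stop("no usable (ungapped, unambiguous) sites",
                        call. = FALSE)
  P <- cnt$ts / cnt$L; Q <- cnt$tv / cnt$L
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

# normalize an alignment (named character vector, DNAStringSet, or
# character matrix with rownames) into a character matrix rows = taxa
.as_aln_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    if (methods::is(alignment, "XStringSet"))
      alignment <- stats::setNames(as.character(alignment), names(alignment))
    stopifnot(is.character(alignment))
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequences differ in length", call. = FALSE)
    m <- do.call(rbind, lapply(alignment, function(s) .chars(toupper(s))))
    rownames(m) <- names(alignment) %||%
      paste0("seq", seq_along(alignment))
  }
  if (nrow(m) < 2L) stop("alignment needs at least 2 sequences",
                         call. = FALSE)
  m
}

#' Pairwise K2P distance matrix for one marker
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences, a `DNAStringSet`, or a character matrix.
#' @param marker optional marker name stored as an attribute.
#' @return symmetric numeric matrix with zero diagonal; undefined
#'   distances are NA.
#' @export
k2p_matrix <- function(alignment, marker = NULL) {
  m <- .as_aln_matrix(alignment)
  ids <- rownames(m)
  k <- nrow(m)
  d <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d[i, j] <- d[j, i] <- k2p_distance(m[i, ], m[j, ])
  }
  attr(d, "marker") <- marker
  d
}

#' Read/write a square distance matrix as TSV
#'
#' The TSV has individual ids as both the first column ("id") and the
#' header; this is the interchange format used for typed-in published
#' distance tables.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_distance_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  if (!identical(rownames(m), colnames(m)))
    stop(sprintf("%s: row and column ids differ", path), call. = FALSE)
  m
}

#' @rdname read_distance_tsv
#' @param d numeric matrix.
#' @export
write_distance_tsv <- function(d, path) {
  tab <- data.frame(id = rownames(d), round(d, 4), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Delimit species groups from per-marker distance matrices
#'
#' Builds a graph over individuals with an edge (i, j) whenever the
#' distances satisfy the rule -- by default d < threshold for *every*
#' marker ("all"); "any" requires a single marker below threshold --
#' and returns the connected components (single linkage) as numbered
#' groups in first-seen individual order. Undefined (NA) distances count
#' as above threshold.
#'
#' Default thresholds are the recommended tick species boundaries:
#' 0.0525 for rrnL and 0.0613 for COX1.
#'
#' @param matrices named list of distance matrices (names = markers),
#'   all over the same individuals.
#' @param thresholds named numeric vector of per-marker thresholds.
#' @param rule "all" (default) or "any".
#' @return list with `groups` (named list group number -> ids) and
#'   `membership` (named integer vector).
#' @export
delimit_species_groups <- function(matrices,
                                   thresholds = c(rrnL = 0.0525, COX1 = 0.0613),
                                   rule = c("all", "any")) {
  rule <- match.arg(rule)
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  if (is.null(names(matrices)) || any(!nzchar(names(matrices))))
    stop("matrices must be a named list (marker names)", call. = FALSE)
  miss <- setdiff(names(matrices), names(thresholds))
  if (length(miss) > 0L)
    stop(sprintf("no threshold supplied for marker(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (any(thresholds <= 0)) stop("thresholds must be positive", call. = FALSE)
  ids <- rownames(matrices[[1]])
  for (m in matrices) {
    if (!identical(sort(rownames(m)), sort(ids)))
      stop("all matrices must share the same individual set", call. = FALSE)
  }
  k <- length(ids)
  below <- lapply(names(matrices), function(mk) {
    d <- matrices[[mk]][ids, ids]
    ok <- d < thresholds[[mk]]
    ok[is.na(ok)] <- FALSE  # undefined distance = above threshold
    ok
  })
  adj <- Reduce(if (rule == "all") `&` else `|`, below)
  diag(adj) <- TRUE
  # connected components, numbering by first-seen order
  membership <- stats::setNames(rep(NA_integer_, k), ids)
  g <- 0L
  for (i in seq_len(k)) {
    if (!is.na(membership[i])) next
    g <- g + 1L
    queue <- i
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(membership[v])) next
      membership[v] <- g
      queue <- c(queue, which(adj[v, ] & is.na(membership)))
    }
  }
  groups <- split(ids, membership)
  names(groups) <- as.character(seq_along(groups))
  list(groups = groups, membership = membership)
}
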