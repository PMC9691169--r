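# Mitogenome record container. Coordinates are 0-based half-open on the
# heavy strand (the strand the flat file prints) throughout the package;
# GenBank I/O converts 1-based inclusive coordinates at the boundary.

#' Construct a gene feature
#'
#' @param name gene identifier; canonical ids get their category
#'   automatically, anything else is kept with category "other".
#' @param start,end 0-based half-open coordinates on the heavy strand.
#'   For a feature that wraps the origin of the circular genome,
#'   `start > end` together with `wraps_origin = TRUE`: the feature runs
#'   from `start` to the end of the sequence and continues from 0 to `end`.
#' @param strand +1 (heavy) or -1 (light).
#' @param wraps_origin logical; feature spans the origin.
#' @return one-row data.frame with columns name, start, end, strand,
#'   category, wraps_origin.
#' @export
gene_feature <- function(name, start, end, strand = 1L, wraps_origin = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            strand %in% c(1L, -1L))
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || end < 0L) stop("negative coordinate", call. = FALSE)
  if (!wraps_origin && end <= start)
    stop(sprintf("feature %s: end (%d) must exceed start (%d)",
                 name, end, start), call. = FALSE)
  data.frame(name = name, start = start, end = end,
             strand = as.integer(strand),
             category = gene_category(name),
             wraps_origin = isTRUE(wraps_origin),
             stringsAsFactors = FALSE)
}

#' Construct an annotated mitogenome record
#'
#' @param id accession-like identifier.
#' @param sequence nucleotide sequence (IUPAC alphabet; upper-cased).
#' @param features data.frame of features as built by [gene_feature()]
#'   (rows may be rbind-ed), or NULL.
#' @param organism organism name.
#' @param circular logical, default TRUE.
#' @return object of class `mitogenome`.
#' @export
mitogenome_record <- function(id, sequence, features = NULL,
                              organism = NA_character_, circular = TRUE) {
  sequence <- .clean_seq(sequence)
  n <- nchar(sequence)
  if (is.null(features))
    features <- gene_feature("CR", 0, 1)[0, ]
  stopifnot(is.data.frame(features))
  if (nrow(features) > 0L) {
    if (any(features$start < 0L) || any(features$start >= n) ||
        any(features$end > n) || any(features$end < 0L))
      stop(sprintf("record %s: feature coordinates outside sequence [0, %d)",
                   id, n), call. = FALSE)
    bad_wrap <- features$wraps_origin & !circular
    if (any(bad_wrap))
      stop(sprintf("record %s: origin-wrapping feature on a linear record", id),
           call. = FALSE)
    canon <- features$name[features$category != "other"]
    dup <- canon[duplicated(canon)]
    if (length(dup) > 0L)
      stop(sprintf("record %s: duplicated canonical feature(s): %s",
                   id, paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  structure(list(id = as.character(id), organism = organism,
                 sequence = sequence, circular = isTRUE(circular),
                 features = features),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s%s: %s bp, %s, %d feature(s)\n",
              x$id,
              if (is.na(x$organism)) "" else paste0(" (", x$organism, ")"),
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

#' Genome length of a record
#' @param record a `mitogenome`.
#' @return integer length in bases.
#' @export
genome_length <- function(record) nchar(record$sequence)

# span length of a feature row, accounting for origin wrap
.feature_span <- function(feat, n) {
  ifelse(feat$wraps_origin, (n - feat$start) + feat$end, feat$end - feat$start)
}

#' Extract a gene's sequence in coding orientation
#'
#' Returns the forward slice for heavy-strand (+1) features and the
#' reverse complement for light-strand (-1) features. Origin-wrapping
#' features are re-joined (tail then head) before orientation.
#'
#' @param record a `mitogenome`.
#' @param name canonical gene id of the feature to extract.
#' @return character scalar nucleotide sequence (5'->3' of the gene).
#' @export
extract_gene_sequence <- function(record, name) {
  i <- which(record$features$name == name)
  if (length(i) == 0L)
    stop(sprintf("record %s has no feature '%s'", record$id, name),
         call. = FALSE)
  f <- record$features[i[1L], ]
  n <- genome_length(record)
  s <- if (f$wraps_origin) {
    paste0(substr(record$sequence, f$start + 1L, n),
           substr(record$sequence, 1L, f$end))
  } else {
    substr(record$sequence, f$start + 1L, f$end)
  }
  if (f$strand == -1L) revcomp(s) else s
}

#' Start/stop-codon quality report for the 13 protein-coding genes
#'
#' Arthropod mitochondrial PCGs start with ATA/ATT/ATC/ATG; stops are the
#' canonical TAA/TAG or a truncated single trailing T (completed to TAA by
#' post-transcriptional polyadenylation). Deviations are flagged, never
#' fatal.
#'
#' @param record a `mitogenome`.
#' @return data.frame with columns gene, length, start_codon, stop_codon,
#'   start_ok, stop_ok, truncated_stop.
#' @export
validate_pcg_codons <- function(record) {
  pcgs <- intersect(.PCGS, record$features$name)
  rows <- lapply(pcgs, function(g) {
    s <- extract_gene_sequence(record, g)
    len <- nchar(s)
    start_codon <- substr(s, 1L, 3L)
    rem <- len %% 3L
    if (rem == 0L) {
      stop_codon <- substr(s, len - 2L, len)
      truncated <- FALSE
      stop_ok <- stop_codon %in% c("TAA", "TAG")
    } else if (rem == 1L) {
      stop_codon <- substr(s, len, len)
      truncated <- TRUE
      stop_ok <- stop_codon == "T"
    } else {
      stop_codon <- substr(s, len - 1L, len)
      truncated <- FALSE
      stop_ok <- FALSE
    }
    data.frame(gene = g, length = len, start_codon = start_codon,
               stop_codon = stop_codon,
               start_ok = start_codon %in% c("ATA", "ATT", "ATC", "ATG"),
               stop_ok = stop_ok, truncated_stop = truncated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
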