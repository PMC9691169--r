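# GenBank flat-file and FASTA/TSV input-output. GenBank prints 1-based
# inclusive coordinates; internally everything is 0-based half-open on the
# heavy strand, so conversion happens exactly here.

.GB_KEYS <- c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature", "rep_origin")

#' Read annotated mitogenomes from a GenBank flat file
#'
#' Parses LOCUS/FEATURES/ORIGIN blocks. Feature locations
#' `complement(a..b)` become strand -1; `join(a..N,1..b)` spanning the
#' origin of a circular record becomes a single feature with
#' `wraps_origin = TRUE`. Gene labels (from `/gene`, else `/product`,
#' else `/note`) are passed through [normalize_gene_name()]; labels that
#' cannot be mapped are retained verbatim with category "other". `gene`
#' and `source` keys are skipped (their spans duplicate the CDS/tRNA/rRNA
#' features).
#'
#' @param path file path.
#' @return list of `mitogenome` records.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "//")
  if (length(ends) == 0L) stop(sprintf("%s: no record terminator '//' found",
                                       path), call. = FALSE)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_along(ends), function(k) {
    .parse_gb_record(lines[starts[k]:ends[k]], path)
  })
}

.parse_gb_record <- function(lines, path) {
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1L)
    stop(sprintf("%s: malformed record, expected one LOCUS line", path),
         call. = FALSE)
  locus <- strsplit(trimws(lines[locus_i]), "\\s+")[[1]]
  id <- locus[2]
  circular <- any(tolower(locus) == "circular")

  organism <- NA_character_
  org_i <- grep("^\\s{2}ORGANISM", lines)
  if (length(org_i) >= 1L)
    organism <- trimws(sub("^\\s*ORGANISM\\s*", "", lines[org_i[1]]))

  # ORIGIN .. end
  ori_i <- grep("^ORIGIN", lines)
  if (length(ori_i) != 1L)
    stop(sprintf("%s (%s): record lacks an ORIGIN sequence block", path, id),
         call. = FALSE)
  seq_lines <- lines[(ori_i + 1L):length(lines)]
  seq_lines <- seq_lines[trimws(seq_lines) != "//"]
  sequence <- toupper(gsub("[0-9 /]", "", paste(seq_lines, collapse = "")))

  # FEATURES block
  feats <- NULL
  ft_i <- grep("^FEATURES", lines)
  if (length(ft_i) == 1L && ft_i + 1L < ori_i) {
    block <- lines[(ft_i + 1L):(ori_i - 1L)]
    feats <- .parse_gb_features(block, id, nchar(sequence), circular, path)
  }
  mitogenome_record(id = id, sequence = sequence, features = feats,
                    organism = organism, circular = circular)
}

.parse_gb_features <- function(block, id, n, circular, path) {
  # a new feature starts with a key in column 6 (5 leading spaces, then
  # non-space); qualifier/continuation lines are indented further
  is_new <- grepl("^\\s{5}\\S", block)
  idx <- which(is_new)
  rows <- list()
  for (k in seq_along(idx)) {
    from <- idx[k]
    to <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
    head_parts <- strsplit(trimws(block[from]), "\\s+")[[1]]
    key <- head_parts[1]
    loc <- paste(head_parts[-1], collapse = "")
    body <- if (to > from) block[(from + 1L):to] else character(0)
    # location may continue onto following lines until the first qualifier
    qual_start <- grep("^\\s+/", body)
    extra <- if (length(qual_start) == 0L) body
             else if (qual_start[1] > 1L) body[seq_len(qual_start[1] - 1L)]
             else character(0)
    loc <- paste0(loc, paste(trimws(extra), collapse = ""))
    if (!key %in% .GB_KEYS) next
    quals <- body[grepl("^\\s+/", body)]
    label <- .gb_qualifier(quals, "gene") %||%
             .gb_qualifier(quals, "product") %||%
             .gb_qualifier(quals, "note")
    if (key == "D-loop" && is.null(label)) label <- "CR"
    if (is.null(label)) next
    name <- tryCatch(normalize_gene_name(label), error = function(e) label)
    parsed <- .parse_gb_location(loc, n, circular, id, path)
    if (any(duplicated_name <- vapply(rows, function(r) r$name == name,
                                      logical(1))))
      next  # keep first annotation of a gene (e.g. gene + CDS duplicates)
    rows[[length(rows) + 1L]] <-
      gene_feature(name, parsed$start, parsed$end, parsed$strand,
                   parsed$wraps_origin)
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.gb_qualifier <- function(quals, what) {
  pat <- sprintf("^\\s*/%s=", what)
  hit <- grep(pat, quals, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  v <- sub(pat, "", hit[1])
  gsub("\"", "", trimws(v))
}

# Convert a GenBank location string to internal coordinates.
.parse_gb_location <- function(loc, n, circular, id, path) {
  strand <- 1L
  raw <- loc
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    rng <- lapply(parts, .parse_gb_range)
    if (length(rng) == 2L && rng[[1]]$b == n && rng[[2]]$a == 1L && circular) {
      wraps <- TRUE
      a <- rng[[1]]$a; b <- rng[[2]]$b
    } else if (length(rng) == 1L) {
      a <- rng[[1]]$a; b <- rng[[1]]$b
    } else {
      stop(sprintf("%s (%s): unsupported join() location '%s'", path, id, raw),
           call. = FALSE)
    }
    start <- a - 1L; end <- b
  } else {
    r <- .parse_gb_range(loc)
    start <- r$a - 1L; end <- r$b
  }
  if (start < 0L || (!wraps && end > n) || (wraps && end > n))
    stop(sprintf("%s (%s): feature location '%s' outside sequence of %d bp",
                 path, id, raw, n), call. = FALSE)
  list(start = start, end = end, strand = strand, wraps_origin = wraps)
}

.parse_gb_range <- function(txt) {
  txt <- gsub("[<>]", "", txt)
  m <- regmatches(txt, regexec("^([0-9]+)\\.\\.([0-9]+)$", txt))[[1]]
  if (length(m) == 0L) {
    m1 <- regmatches(txt, regexec("^([0-9]+)$", txt))[[1]]
    if (length(m1) == 0L)
      stop(sprintf("cannot parse location range '%s'", txt), call. = FALSE)
    a <- as.integer(m1[2]); return(list(a = a, b = a))
  }
  list(a = as.integer(m[2]), b = as.integer(m[3]))
}

.GB_KEY_FOR <- function(category) {
  switch(category, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
         CR = "D-loop", "misc_feature")
}

#' Write mitogenome records as a GenBank flat file
#'
#' Inverse of [read_genbank()] on the feature subset this package models:
#' names, coordinates, strands and sequence round-trip exactly.
#'
#' @param records a `mitogenome` or list of them.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "mitogenome")) records <- list(records)
  out <- character(0)
  for (rec in records) {
    n <- genome_length(rec)
    out <- c(out, sprintf(
      "LOCUS       %-16s %d bp    DNA     %-8s INV",
      rec$id, n, if (rec$circular) "circular" else "linear"))
    out <- c(out, sprintf("DEFINITION  %s mitochondrion, complete genome.",
                          if (is.na(rec$organism)) rec$id else rec$organism))
    if (!is.na(rec$organism))
      out <- c(out, "SOURCE      mitochondrion",
               sprintf("  ORGANISM  %s", rec$organism))
    out <- c(out, "FEATURES             Location/Qualifiers")
    out <- c(out, sprintf("     %-16s%s", "source", sprintf("1..%d", n)))
    if (nrow(rec$features) > 0L) {
      for (i in seq_len(nrow(rec$features))) {
        f <- rec$features[i, ]
        loc <- if (f$wraps_origin)
          sprintf("join(%d..%d,1..%d)", f$start + 1L, n, f$end)
        else sprintf("%d..%d", f$start + 1L, f$end)
        if (f$strand == -1L) loc <- sprintf("complement(%s)", loc)
        key <- .GB_KEY_FOR(f$category)
        out <- c(out, sprintf("     %-16s%s", key, loc),
                 sprintf("                     /gene=\"%s\"", f$name))
      }
    }
    out <- c(out, "ORIGIN")
    s <- tolower(rec$sequence)
    for (off in seq(1L, n, by = 60L)) {
      chunk <- substr(s, off, min(off + 59L, n))
      groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", off, paste(groups, collapse = " ")))
    }
    out <- c(out, "//")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#' @param path file path.
#' @return named character vector of upper-cased sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)),
                  sub("\\s.*$", "", names(x)))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector (or `mitogenome` list).
#' @param path output path.
#' @param width line width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "mitogenome")) seqs <- list(seqs)
  if (is.list(seqs) && all(vapply(seqs, inherits, logical(1), "mitogenome")))
    seqs <- stats::setNames(vapply(seqs, `[[`, character(1), "sequence"),
                            vapply(seqs, `[[`, character(1), "id"))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read features from a tabular (TSV) file
#'
#' Columns: id, name, start, end, strand (internal 0-based half-open
#' convention), plus optional wraps_origin. Used together with a FASTA of
#' the same ids as a light-weight alternative to GenBank flat files.
#'
#' @param path TSV path.
#' @param sequences named character vector of sequences keyed by id.
#' @return list of `mitogenome` records.
#' @export
read_feature_tsv <- function(path, sequences) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "start", "end", "strand")
  if (!all(need %in% names(tab)))
    stop(sprintf("feature TSV must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  if (!"wraps_origin" %in% names(tab)) tab$wraps_origin <- FALSE
  lapply(unique(tab$id), function(rid) {
    if (!rid %in% names(sequences))
      stop(sprintf("no sequence supplied for record id '%s'", rid),
           call. = FALSE)
    sub <- tab[tab$id == rid, ]
    feats <- do.call(rbind, c(lapply(seq_len(nrow(sub)), function(i)
      gene_feature(sub$name[i], sub$start[i], sub$end[i],
                   as.integer(sub$strand[i]), isTRUE(sub$wraps_origin[i]))),
      list(make.row.names = FALSE)))
    mitogenome_record(rid, sequences[[rid]], feats)
  })
}

#' Write features of records to a tabular (TSV) file
#' @param records list of `mitogenome` records.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_feature_tsv <- function(records, path) {
  if (inherits(records, "mitogenome")) records <- list(records)
  tabs <- lapply(records, function(r)
    cbind(id = r$id, r$features[, c("name", "start", "end", "strand",
                                    "wraps_origin")]))
  utils::write.table(do.call(rbind, tabs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
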