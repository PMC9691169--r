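# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.ACGT <- c("A", "C", "G", "T")

.IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N")

#' Reverse complement of a nucleotide string
#'
#' Accepts the full IUPAC alphabet (upper- or lower-case); returns upper-case.
#'
#' @param seq character scalar nucleotide sequence.
#' @return character scalar, the reverse complement.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic generator entry points route
# through this so that a fixed seed gives byte-identical output.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Validate and upper-case a nucleotide string over the IUPAC alphabet.
.clean_seq <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  s <- gsub("U", "T", s, fixed = TRUE)
  ch <- unique(.chars(s))
  bad <- setdiff(ch, .IUPAC_CHARS)
  if (length(bad) > 0L)
    stop(sprintf("invalid %s character(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  s
}
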