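# Canonical 37-gene + control-region vocabulary for tick (and generally
# arthropod) mitogenomes, and normalization of the heterogeneous labels
# found in public annotations onto it.

.PCGS  <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
            "COX1", "COX2", "COX3", "CYTB", "ATP6", "ATP8")
.TRNAS <- c("trnA", "trnR", "trnN", "trnD", "trnC", "trnQ", "trnE", "trnG",
            "trnH", "trnI", "trnL1", "trnL2", "trnK", "trnM", "trnF",
            "trnP", "trnS1", "trnS2", "trnT", "trnW", "trnY", "trnV")
.RRNAS <- c("rrnS", "rrnL")
.CRS   <- c("CR", "CR2")

#' Canonical mitochondrial gene vocabulary
#'
#' The 13 protein-coding genes, 22 tRNAs (with the two leucine and two
#' serine isoacceptors distinguished as trnL1/trnL2 and trnS1/trnS2),
#' two rRNAs, and the control region(s).
#'
#' @return character vector of canonical gene identifiers.
#' @export
canonical_genes <- function() c(.PCGS, .TRNAS, .RRNAS, .CRS)

#' Category of a canonical gene id
#'
#' @param name canonical gene id(s).
#' @return character vector: "PCG", "tRNA", "rRNA", "CR", or "other" for
#'   identifiers outside the canonical vocabulary.
#' @export
gene_category <- function(name) {
  vapply(name, function(g) {
    if (g %in% .PCGS) "PCG"
    else if (g %in% .TRNAS) "tRNA"
    else if (g %in% .RRNAS) "rRNA"
    else if (g %in% .CRS) "CR"
    else "other"
  }, character(1), USE.NAMES = FALSE)
}

# amino-acid 3-letter -> canonical tRNA id (leucine/serine need anticodon)
.AA3 <- c(ala = "trnA", arg = "trnR", asn = "trnN", asp = "trnD",
          cys = "trnC", gln = "trnQ", glu = "trnE", gly = "trnG",
          his = "trnH", ile = "trnI", lys = "trnK", met = "trnM",
          phe = "trnF", pro = "trnP", thr = "trnT", trp = "trnW",
          tyr = "trnY", val = "trnV")

.SYNONYMS <- local({
  syn <- list(
    ND1 = c("nd1", "nad1", "nadh1", "nadh dehydrogenase subunit 1"),
    ND2 = c("nd2", "nad2", "nadh2", "nadh dehydrogenase subunit 2"),
    ND3 = c("nd3", "nad3", "nadh3", "nadh dehydrogenase subunit 3"),
    ND4 = c("nd4", "nad4", "nadh4", "nadh dehydrogenase subunit 4"),
    ND4L = c("nd4l", "nad4l", "nadh4l", "nadh dehydrogenase subunit 4l"),
    ND5 = c("nd5", "nad5", "nadh5", "nadh dehydrogenase subunit 5"),
    ND6 = c("nd6", "nad6", "nadh6", "nadh dehydrogenase subunit 6"),
    COX1 = c("cox1", "coi", "co1", "cox i", "cytochrome c oxidase subunit 1",
             "cytochrome c oxidase subunit i", "cytochrome oxidase subunit 1"),
    COX2 = c("cox2", "coii", "co2", "cox ii", "cytochrome c oxidase subunit 2",
             "cytochrome c oxidase subunit ii"),
    COX3 = c("cox3", "coiii", "co3", "cox iii", "cytochrome c oxidase subunit 3",
             "cytochrome c oxidase subunit iii"),
    CYTB = c("cytb", "cob", "cyt b", "cytochrome b"),
    ATP6 = c("atp6", "atpase6", "atpase 6", "atp synthase f0 subunit 6"),
    ATP8 = c("atp8", "atpase8", "atpase 8", "atp synthase f0 subunit 8"),
    rrnS = c("rrns", "12s", "12s rrna", "12s ribosomal rna", "s-rrna",
             "srrna", "small subunit ribosomal rna", "rrn12"),
    rrnL = c("rrnl", "16s", "16s rrna", "16s ribosomal rna", "l-rrna",
             "lrrna", "large subunit ribosomal rna", "rrn16"),
    CR = c("cr", "d-loop", "control region", "a+t rich region",
           "a+t-rich region", "at rich region", "at-rich region",
           "misc control region"),
    CR2 = c("cr2", "control region 2", "d-loop 2")
  )
  for (id in names(.AA3)) syn[[.AA3[[id]]]] <- character(0)
  syn
})

#' Normalize a free-text gene label to the canonical vocabulary
#'
#' Maps the synonym spellings commonly seen in GenBank tick records
#' (e.g. "nad1", "COI", "12S ribosomal RNA", "tRNA-Leu(CUN)",
#' "A+T rich region") onto the canonical identifiers. Matching is
#' case-insensitive. The leucine/serine tRNA isoacceptors are resolved by
#' their anticodon class: (CUN) -> trnL1, (UUR) -> trnL2, (AGN) -> trnS1,
#' (UCN) -> trnS2.
#'
#' @param raw free-text gene label (character scalar).
#' @return canonical gene id (character scalar).
#' @export
#' @examples
#' normalize_gene_name("tRNA-Leu(CUN)")  # "trnL1"
#' normalize_gene_name("nad4l")          # "ND4L"
normalize_gene_name <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(trimws(raw))) stop("empty gene label", call. = FALSE)
  lab <- tolower(trimws(raw))
  lab <- gsub("\\s+", " ", lab)

  # exact canonical id (case-insensitive)
  canon <- canonical_genes()
  hit <- canon[tolower(canon) == lab]
  if (length(hit) == 1L) return(hit)

  # synonym table
  for (id in names(.SYNONYMS))
    if (lab %in% .SYNONYMS[[id]]) return(id)

  # tRNA forms: trnX, trn-X, tRNA-Xaa, tRNA-Xaa(anticodon), trnL(uur), ...
  m <- regmatches(lab, regexec(
    "^t?rna[- ]?([a-z]{3})\\s*(?:\\(([a-z]{3})\\))?$", lab))[[1]]
  if (length(m) == 0L)
    m <- regmatches(lab, regexec(
      "^trn[- ]?([a-z][0-9]?)\\s*(?:\\(([a-z]{3})\\))?$", lab))[[1]]
  if (length(m) > 0L) {
    aa <- m[2]; anticodon <- m[3]
    if (nchar(aa) == 3L && aa %in% names(.AA3)) return(.AA3[[aa]])
    one <- NULL
    if (nchar(aa) == 3L && aa %in% c("leu", "ser")) {
      one <- if (aa == "leu") "L" else "S"
    } else if (nchar(aa) <= 2L) {
      one <- toupper(substr(aa, 1, 1))
      num <- sub("^[a-z]", "", aa)
      if (nzchar(num)) return(.resolve_trna(one, num, raw))
    }
    if (!is.null(one)) {
      if (!one %in% c("L", "S")) {
        id <- paste0("trn", one)
        if (id %in% .TRNAS) return(id)
      } else if (nzchar(anticodon) && !is.na(anticodon)) {
        ac <- toupper(gsub("u", "t", anticodon))
        if (one == "L") return(if (ac %in% c("CTN", "TAG")) "trnL1" else "trnL2")
        if (one == "S") return(if (ac %in% c("AGN", "GCT")) "trnS1" else "trnS2")
      }
    }
  }
  stop(sprintf("cannot map gene label to canonical vocabulary: '%s'", raw),
       call. = FALSE)
}

.resolve_trna <- function(one, num, raw) {
  id <- paste0("trn", one, num)
  if (id %in% .TRNAS) return(id)
  stop(sprintf("cannot map gene label to canonical vocabulary: '%s'", raw),
       call. = FALSE)
}
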