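# Seeded generator of annotated mitogenomes, divergent sequence pairs, and
# grouped marker alignments, with a ground-truth log for every planted
# feature. The stated world: circular ~14.7 kb genomes, 37 genes + CR laid
# out on the ancestral arthropod arrangement, i.i.d. background at the
# family-average A+T fraction 0.78 with AT-skew -0.017 and GC-skew -0.172.

.DEFAULT_GENE_LENGTHS <- local({
  g <- c(ND1 = 921L, ND2 = 960L, ND3 = 330L, ND4 = 1320L, ND4L = 270L,
         ND5 = 1650L, ND6 = 432L, COX1 = 1530L, COX2 = 660L, COX3 = 780L,
         CYTB = 1071L, ATP6 = 660L, ATP8 = 156L,
         rrnL = 1250L, rrnS = 700L, CR = 340L, CR2 = 340L)
  for (t in .TRNAS) g[[t]] <- 66L
  g
})

#' Simulation parameters for the synthetic mitogenome generator
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @param length_target genome length target in bp; the default (NULL)
#'   uses the summed gene lengths plus 218 bp of intergenic slack, which
#'   lands near 14.7 kb for the standard 37-gene + CR template. Slack over
#'   the summed gene lengths is distributed as intergenic spacers.
#' @param at_fraction target A+T fraction (default 0.78).
#' @param at_skew,gc_skew target strand skews of the background
#'   (defaults -0.017 and -0.172).
#' @param order gene arrangement to lay out (a `gene_order`; default the
#'   ancestral arthropod T1).
#' @param gene_lengths named integer vector of per-gene lengths.
#' @param planted_ssrs list of `list(motif=, repeats=, host=)` entries;
#'   `host` is a feature name or "intergenic" (largest spacer).
#' @param planted_motifs list of `list(pattern=, host=, mismatches=0,
#'   strand=NULL, offset=NULL)` entries; `host` is a feature name,
#'   "intergenic", or `list(downstream_of=<gene>, offset=<bases>)`.
#' @param id,organism record metadata.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, length_target = NULL,
                       at_fraction = 0.78, at_skew = -0.017,
                       gc_skew = -0.172, order = ancestral_arrangement(),
                       gene_lengths = .DEFAULT_GENE_LENGTHS,
                       planted_ssrs = list(), planted_motifs = list(),
                       id = "SYN000001", organism = "Ixodes syntheticus") {
  stopifnot(at_fraction > 0, at_fraction < 1,
            abs(at_skew) <= 1, abs(gc_skew) <= 1)
  structure(list(seed = as.integer(seed),
                 length_target = if (is.null(length_target)) NULL
                                 else as.integer(length_target),
                 at_fraction = at_fraction, at_skew = at_skew,
                 gc_skew = gc_skew, order = order,
                 gene_lengths = gene_lengths,
                 planted_ssrs = planted_ssrs,
                 planted_motifs = planted_motifs,
                 id = id, organism = organism),
            class = "sim_params")
}

.base_probs <- function(at, at_skew, gc_skew) {
  gc <- 1 - at
  c(A = at / 2 * (1 + at_skew), T = at / 2 * (1 - at_skew),
    G = gc / 2 * (1 + gc_skew), C = gc / 2 * (1 - gc_skew))
}

.sample_background <- function(n, probs) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# overwrite seq[at..at+nchar(what)-1] (0-based `at`) in a chars vector
.splice <- function(ch, at0, what) {
  w <- .chars(what)
  ch[(at0 + 1L):(at0 + length(w))] <- w
  ch
}

#' Simulate one annotated mitogenome with ground truth
#'
#' Draws an i.i.d. heavy-strand background hitting the A+T and skew
#' targets, lays the genes of `params$order` in order from position 0 with
#' random intergenic spacers, rewrites PCG start/stop codons so the codon
#' QC passes, then splices in the requested SSR tracts and degenerate
#' motif instances. Flanking bases of every planted SSR are set so the
#' tract is maximal exactly at its planted coordinates, and recovery by
#' [find_perfect_ssrs()] is verified before returning.
#'
#' @param params a [sim_params()].
#' @return list(record = `mitogenome`, truth = list(ssrs, motifs, params)).
#' @export
simulate_mitogenome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_local_seed(params$seed, {
    ord <- params$order
    lens <- vapply(ord$genes, function(g) {
      if (!g %in% names(params$gene_lengths))
        stop(sprintf("no length for gene '%s'", g), call. = FALSE)
      params$gene_lengths[[g]]
    }, integer(1))
    target <- params$length_target %||% (sum(lens) + 218L)
    slack <- target - sum(lens)
    if (slack < 0L)
      stop("length_target smaller than summed gene lengths", call. = FALSE)
    k <- length(lens)
    spacer <- tabulate(sample.int(k, slack, replace = TRUE), nbins = k)
    # downstream-of plants need a noncoding span 3' of the host gene wide
    # enough for offset + pattern; widen that spacer before layout
    for (p in params$planted_motifs) {
      host <- p$host %||% "intergenic"
      if (is.list(host) && !is.null(host$downstream_of)) {
        i <- match(host$downstream_of, ord$genes)
        if (is.na(i)) stop("unknown downstream host gene", call. = FALSE)
        pat <- p$pattern %||% tick_box_pattern()
        if (is.character(pat)) pat <- parse_iupac(pat)
        need <- (host$offset %||% 20L) + pat$length + 2L
        j <- if (ord$signs[i] == 1L) i else if (i > 1L) i - 1L else k
        spacer[j] <- max(spacer[j], need)
      } else if (identical(host, "intergenic")) {
        # an "intergenic" context needs clearance beyond the downstream
        # window on both sides; widen the largest spacer accordingly
        pat <- p$pattern %||% tick_box_pattern()
        if (is.character(pat)) pat <- parse_iupac(pat)
        j <- which.max(spacer)
        spacer[j] <- max(spacer[j], 2L * 100L + pat$length + 4L)
      }
    }
    # intergenic SSR plants also need room in the largest spacer
    for (p in params$planted_ssrs) {
      if (identical(p$host %||% "intergenic", "intergenic")) {
        j <- which.max(spacer)
        spacer[j] <- spacer[j] + nchar(p$motif) * as.integer(p$repeats) + 4L
      }
    }
    # layout: gene i occupies [pos, pos+len), then spacer[i]
    starts <- integer(k); pos <- 0L
    for (i in seq_len(k)) {
      starts[i] <- pos
      pos <- pos + lens[i] + spacer[i]
    }
    n <- pos
    probs <- .base_probs(params$at_fraction, params$at_skew, params$gc_skew)
    ch <- .chars(.sample_background(n, probs))

    feats <- do.call(rbind, c(lapply(seq_len(k), function(i)
      gene_feature(ord$genes[i], starts[i], starts[i] + lens[i],
                   ord$signs[i])), list(make.row.names = FALSE)))

    # start/stop codons for the 13 PCGs (in coding orientation)
    for (i in which(feats$name %in% .PCGS)) {
      start_codon <- sample(c("ATA", "ATT", "ATC", "ATG"), 1L)
      if (feats$strand[i] == 1L) {
        ch <- .splice(ch, feats$start[i], start_codon)
        ch <- .splice(ch, feats$end[i] - 3L, "TAA")
      } else {
        ch <- .splice(ch, feats$end[i] - 3L, revcomp(start_codon))
        ch <- .splice(ch, feats$start[i], revcomp("TAA"))
      }
    }

    spacer_iv <- data.frame(start = starts + lens, len = spacer)
    host_span <- function(host) {
      if (identical(host, "intergenic")) {
        j <- which.max(spacer_iv$len)
        c(spacer_iv$start[j], spacer_iv$start[j] + spacer_iv$len[j])
      } else {
        f <- feats[feats$name == host, ]
        if (nrow(f) == 0L) stop(sprintf("unknown host '%s'", host),
                                call. = FALSE)
        c(f$start[1], f$end[1])
      }
    }

    # --- planted SSRs ------------------------------------------------
    ssr_rows <- list()
    for (p in params$planted_ssrs) {
      motif <- toupper(p$motif); reps <- as.integer(p$repeats)
      if (!.is_primitive(motif)) stop("planted motif must be primitive",
                                      call. = FALSE)
      tract <- strrep(motif, reps)
      m <- nchar(motif); tl <- nchar(tract)
      sp <- host_span(p$host %||% "intergenic")
      if (sp[2] - sp[1] < tl + 2L)
        stop(sprintf("host '%s' too small for planted SSR", p$host),
             call. = FALSE)
      s0 <- sp[1] + sample.int(sp[2] - sp[1] - tl - 1L, 1L)  # leave flanks
      ch <- .splice(ch, s0, tract)
      # break flanks so the tract is maximal exactly at [s0, s0+tl)
      lf <- substr(motif, m, m)   # base that would extend leftwards
      rf <- substr(motif, 1L, 1L) # base that would extend rightwards
      ch[s0] <- sample(setdiff(.ACGT, lf), 1L)
      ch[s0 + tl + 1L] <- sample(setdiff(.ACGT, rf), 1L)
      ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
        start = s0, end = s0 + tl, motif = motif,
        std_motif = standardize_motif(motif), repeats = reps,
        host = if (is.character(p$host %||% "intergenic"))
          (p$host %||% "intergenic") else "intergenic",
        stringsAsFactors = FALSE)
    }

    # --- planted motif instances ------------------------------------
    motif_rows <- list()
    for (p in params$planted_motifs) {
      pat <- p$pattern %||% tick_box_pattern()
      if (is.character(pat)) pat <- parse_iupac(pat)
      L <- pat$length
      mism <- as.integer(p$mismatches %||% 0L)
      realization <- vapply(pat$allowed, function(ok) sample(ok, 1L),
                            character(1))
      if (mism > 0L) {
        cand <- which(vapply(pat$allowed, length, integer(1)) < 4L)
        if (length(cand) < mism)
          stop("cannot realize that many mismatches", call. = FALSE)
        at <- sample(cand, mism)
        for (j in at)
          realization[j] <- sample(setdiff(.ACGT, pat$allowed[[j]]), 1L)
      }
      realization <- paste(realization, collapse = "")
      host <- p$host %||% "intergenic"
      if (is.list(host) && !is.null(host$downstream_of)) {
        f <- feats[feats$name == host$downstream_of, ]
        if (nrow(f) == 0L) stop("unknown downstream host gene", call. = FALSE)
        offset <- host$offset %||% 20L
        strand <- p$strand %||% f$strand[1]
        s0 <- if (f$strand[1] == 1L) f$end[1] + offset
              else f$start[1] - offset - L
        context <- paste("downstream of", host$downstream_of)
      } else {
        sp <- host_span(host)
        if (sp[2] - sp[1] < L) stop("host too small for motif", call. = FALSE)
        if (identical(host, "intergenic")) {
          s0 <- (sp[1] + sp[2] - L) %/% 2L  # centered: clear of both genes
          strand <- p$strand %||% 1L
          context <- "intergenic"
        } else {
          off <- sample.int(sp[2] - sp[1] - L + 1L, 1L) - 1L
          s0 <- sp[1] + off
          f <- feats[feats$name == host, ]
          strand <- p$strand %||% f$strand[1]
          context <- paste("within", host)
        }
      }
      written <- if (strand == -1L) revcomp(realization) else realization
      ch <- .splice(ch, s0, written)
      motif_rows[[length(motif_rows) + 1L]] <- data.frame(
        start = s0, end = s0 + L, strand = as.integer(strand),
        realization = realization, mismatches = mism, context = context,
        stringsAsFactors = FALSE)
    }

    record <- mitogenome_record(params$id, paste(ch, collapse = ""),
                                feats, organism = params$organism)
    truth <- list(
      ssrs = if (length(ssr_rows)) do.call(rbind, ssr_rows) else NULL,
      motifs = if (length(motif_rows)) do.call(rbind, motif_rows) else NULL,
      params = params)

    # verify planted SSR recovery (generation contract)
    if (!is.null(truth$ssrs)) {
      found <- find_perfect_ssrs(record)
      for (i in seq_len(nrow(truth$ssrs))) {
        t <- truth$ssrs[i, ]
        hit <- found[found$start == t$start & found$end == t$end &
                     found$std_motif == t$std_motif, ]
        if (nrow(hit) == 0L)
          stop(sprintf("generation error: planted SSR %s x%d at %d not recovered",
                       t$motif, t$repeats, t$start), call. = FALSE)
      }
    }
    list(record = record, truth = truth)
  })
}

#' Evolve a sequence under the Kimura 2-parameter model
#'
#' Applies the exact K2P transition probabilities at total divergence
#' `d_star` (expected substitutions per site) with transition/transversion
#' rate ratio `kappa`, independently per site, so the expected K2P
#' distance between input and output is `d_star`.
#'
#' @param seq nucleotide character scalar (non-ACGT positions are left
#'   untouched).
#' @param d_star target divergence, >= 0 (values above 5 are rejected as
#'   unresolvable in practice).
#' @param kappa transition/transversion rate ratio (> 0, default 2).
#' @param seed optional seed (localized).
#' @return mutated sequence (character scalar).
#' @export
evolve_pair <- function(seq, d_star, kappa = 2, seed = NULL) {
  stopifnot(d_star >= 0, kappa > 0)
  if (d_star > 5) stop("d_star beyond the resolvable range", call. = FALSE)
  run <- function() {
    if (d_star == 0) return(toupper(seq))
    b <- d_star / (kappa + 2)
    a <- kappa * b
    p_ts <- 0.25 + 0.25 * exp(-4 * b) - 0.5 * exp(-2 * (a + b))
    p_tv <- 0.5 - 0.5 * exp(-4 * b)          # both transversions together
    ch <- .chars(toupper(seq))
    n <- length(ch)
    u <- stats::runif(n)
    ts_map <- c(A = "G", G = "A", C = "T", T = "C")
    tv1 <- c(A = "C", G = "C", C = "A", T = "A")
    tv2 <- c(A = "T", G = "T", C = "G", T = "G")
    acgt <- ch %in% .ACGT
    pick_ts <- acgt & u < p_ts
    pick_tv1 <- acgt & u >= p_ts & u < p_ts + p_tv / 2
    pick_tv2 <- acgt & u >= p_ts + p_tv / 2 & u < p_ts + p_tv
    ch[pick_ts] <- ts_map[ch[pick_ts]]
    ch[pick_tv1] <- tv1[ch[pick_tv1]]
    ch[pick_tv2] <- tv2[ch[pick_tv2]]
    paste(ch, collapse = "")
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Apply gene-order rearrangement events
#'
#' Event kinds: "transposition" (move `gene` to the slot after `after`,
#' or a random slot), "inversion" (flip the strand sign of `gene` in
#' place), "cr_duplication" (insert CR2 after `after` or a random slot).
#' Events are applied sequentially and recorded in the returned log.
#'
#' @param order a `gene_order`.
#' @param events list of `list(kind=, gene=, after=)` entries.
#' @param seed optional seed for random placements.
#' @return list(order = rearranged `gene_order`, log = data.frame).
#' @export
apply_rearrangement_events <- function(order, events, seed = NULL) {
  run <- function() {
    genes <- order$genes; signs <- order$signs
    log <- list()
    insert_after <- function(genes, signs, g, s, after) {
      j <- if (is.null(after)) sample.int(length(genes), 1L)
           else match(after, genes)
      if (is.na(j)) stop(sprintf("unknown anchor gene '%s'", after),
                         call. = FALSE)
      list(genes = append(genes, g, after = j),
           signs = append(signs, s, after = j), at = j)
    }
    for (ev in events) {
      kind <- match.arg(ev$kind, c("transposition", "inversion",
                                   "cr_duplication"))
      if (kind == "inversion") {
        i <- match(ev$gene, genes)
        if (is.na(i)) stop(sprintf("unknown gene '%s'", ev$gene),
                           call. = FALSE)
        signs[i] <- -signs[i]
        log[[length(log) + 1L]] <- data.frame(kind = kind, gene = ev$gene,
                                              after = NA_character_)
      } else if (kind == "transposition") {
        i <- match(ev$gene, genes)
        if (is.na(i)) stop(sprintf("unknown gene '%s'", ev$gene),
                           call. = FALSE)
        g <- genes[i]; s <- signs[i]
        genes <- genes[-i]; signs <- signs[-i]
        ins <- insert_after(genes, signs, g, s, ev$after %||% NULL)
        genes <- ins$genes; signs <- ins$signs
        log[[length(log) + 1L]] <- data.frame(kind = kind, gene = ev$gene,
                                              after = genes[ins$at])
      } else {
        if ("CR2" %in% genes) stop("CR2 already present", call. = FALSE)
        ins <- insert_after(genes, signs, "CR2", 1L, ev$after %||% NULL)
        genes <- ins$genes; signs <- ins$signs
        log[[length(log) + 1L]] <- data.frame(kind = kind, gene = "CR2",
                                              after = genes[ins$at])
      }
    }
    list(order = structure(list(id = order$id, genes = genes, signs = signs),
                           class = "gene_order"),
         log = if (length(log)) do.call(rbind, log) else
           data.frame(kind = character(0), gene = character(0),
                      after = character(0)))
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Simulate a grouped marker alignment with known species structure
#'
#' Star-like two-level divergence: a root sequence, one ancestor per
#' group at distance (d_between - d_within)/2 from the root, and tips at
#' d_within/2 from their ancestor, so expected pairwise divergence is
#' d_within inside a group and d_between across groups.
#'
#' @param n_taxa number of sequences.
#' @param length sites.
#' @param d_within,d_between target within/between-group pairwise K2P
#'   divergences (d_within < d_between).
#' @param n_groups number of groups (default 2; taxa split near-equally).
#' @param kappa transition/transversion ratio.
#' @param at_fraction background A+T fraction.
#' @param seed RNG seed.
#' @return list(alignment = named character vector, groups = named integer
#'   membership vector).
#' @export
simulate_marker_alignment <- function(n_taxa, length, d_within, d_between,
                                      n_groups = 2L, kappa = 2,
                                      at_fraction = 0.70, seed = 1L) {
  stopifnot(d_within >= 0, d_between >= d_within, n_taxa >= n_groups)
  with_local_seed(seed, {
    probs <- .base_probs(at_fraction, 0, 0)
    root <- .sample_background(length, probs)
    sizes <- rep(n_taxa %/% n_groups, n_groups)
    extra <- n_taxa %% n_groups
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    aln <- character(0); grp <- integer(0)
    for (g in seq_len(n_groups)) {
      anc <- evolve_pair(root, (d_between - d_within) / 2, kappa)
      for (t in seq_len(sizes[g])) {
        tip <- evolve_pair(anc, d_within / 2, kappa)
        nm <- sprintf("g%d_t%d", g, t)
        aln[nm] <- tip
        grp[nm] <- g
      }
    }
    list(alignment = aln, groups = grp)
  })
}
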