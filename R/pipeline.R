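# Pipeline orchestration: run all analysis stages over a set of records
# and/or alignments from a single config, writing machine-readable TSV and
# JSON outputs plus a run manifest.

.PIPELINE_STAGES <- c("composition", "ssr", "motif", "order",
                      "distance", "group", "diversity")

#' Build a pipeline configuration
#'
#' @param genbank path(s) to GenBank flat files (optional).
#' @param fasta,features paths to a FASTA + feature TSV pair (optional
#'   alternative input route).
#' @param alignments named character vector marker -> aligned FASTA path.
#' @param distance_tsvs named character vector marker -> distance-matrix
#'   TSV path (used by the grouping stage when no alignments are given).
#' @param stages stages to run (subset of composition, ssr, motif, order,
#'   distance, group, diversity).
#' @param ssr_min_repeats minimum repeat counts for motif lengths 1..6.
#' @param motif_pattern IUPAC pattern (default Tick-Box consensus).
#' @param max_mismatch motif mismatch tolerance.
#' @param downstream_window bases counted as downstream for hit context.
#' @param thresholds per-marker species-delimitation thresholds.
#' @param grouping_rule "all" or "any".
#' @param window,step sliding-window size/step for diversity.
#' @param catalog path to an arrangement catalog TSV (optional; T1 is
#'   always included).
#' @param outdir output directory.
#' @param seed seed recorded in the manifest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(genbank = NULL, fasta = NULL, features = NULL,
                            alignments = NULL, distance_tsvs = NULL,
                            stages = .PIPELINE_STAGES,
                            ssr_min_repeats = c(10L, 5L, 4L, 3L, 3L, 3L),
                            motif_pattern = "TTGyrTChwwwTwwGdA",
                            max_mismatch = 1L, downstream_window = 100L,
                            thresholds = c(rrnL = 0.0525, COX1 = 0.0613),
                            grouping_rule = "all",
                            window = 200L, step = 20L,
                            catalog = NULL, outdir = tempfile("mitotick_run_"),
                            seed = 1L) {
  unknown <- setdiff(stages, .PIPELINE_STAGES)
  if (length(unknown) > 0L)
    stop(sprintf("unknown stage(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  for (p in c(genbank, fasta, features, alignments, distance_tsvs, catalog))
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("input path does not exist: %s", p), call. = FALSE)
  structure(list(genbank = genbank, fasta = fasta, features = features,
                 alignments = alignments, distance_tsvs = distance_tsvs,
                 stages = stages, ssr_min_repeats = ssr_min_repeats,
                 motif_pattern = motif_pattern, max_mismatch = max_mismatch,
                 downstream_window = downstream_window,
                 thresholds = thresholds, grouping_rule = grouping_rule,
                 window = window, step = step, catalog = catalog,
                 outdir = outdir, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file; keys are the arguments of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Stages run in dependency order: record input feeds composition, SSR,
#' motif and gene-order stages; alignments (or distance TSVs) feed the
#' distance, grouping and diversity stages. Outputs are written under
#' `config$outdir` and listed, with md5 checksums, in `manifest.json`.
#' A failing stage stops with an error naming the stage; outputs of
#' completed stages are retained.
#'
#' @param config a `pipeline_config` or path to a JSON config.
#' @return invisibly, a list of produced file paths by stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- new.env(parent = emptyenv())  # stage closures write into this
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  records <- NULL
  if (!is.null(config$genbank)) {
    records <- stage("io", do.call(c, lapply(config$genbank, read_genbank)))
  } else if (!is.null(config$fasta) && !is.null(config$features)) {
    records <- stage("io",
                     read_feature_tsv(config$features, read_fasta(config$fasta)))
  }

  path <- function(f) file.path(config$outdir, f)

  if ("composition" %in% config$stages && !is.null(records)) {
    stage("composition", {
      tbl <- genome_gene_table(records)
      out$composition <- .write_tsv(tbl, path("composition.tsv"))
    })
  }
  if ("ssr" %in% config$stages && !is.null(records)) {
    stage("ssr", {
      cfg <- ssr_config(config$ssr_min_repeats)
      loci <- do.call(rbind, lapply(records, find_perfect_ssrs, config = cfg))
      sizes <- stats::setNames(vapply(records, genome_length, numeric(1)),
                               vapply(records, `[[`, character(1), "id"))
      out$ssr_loci <- .write_tsv(loci, path("ssr_loci.tsv"))
      s <- summarize_ssrs(loci, sizes)
      out$ssr_summary <- .write_json(s, path("ssr_summary.json"))
    })
  }
  if ("motif" %in% config$stages && !is.null(records)) {
    stage("motif", {
      pat <- parse_iupac(config$motif_pattern)
      hits <- do.call(rbind, lapply(records, function(r)
        annotate_hits(scan_motif(r, pat, config$max_mismatch), r,
                      config$downstream_window)))
      out$motif_hits <- .write_tsv(hits, path("motif_hits.tsv"))
    })
  }
  if ("order" %in% config$stages && !is.null(records)) {
    stage("order", {
      catalog <- default_catalog()
      if (!is.null(config$catalog))
        catalog <- c(catalog, read_catalog(config$catalog))
      bm <- ancestral_arrangement()
      orders <- lapply(records, extract_gene_order)
      cmps <- lapply(orders, compare_to_benchmark, benchmark = bm)
      summ <- data.frame(
        record_id = vapply(records, `[[`, character(1), "id"),
        type = vapply(orders, assign_arrangement_type, character(1),
                      catalog = catalog),
        rs = vapply(cmps, `[[`, numeric(1), "rs"),
        stringsAsFactors = FALSE)
      out$gene_order <- .write_tsv(summ, path("gene_order.tsv"))
      rf <- rearrangement_frequency(cmps, bm)
      out$rf <- .write_tsv(rf$rf, path("rf.tsv"))
      writeLines(paste(rf$conserved_segment, collapse = ","),
                 path("conserved_segment.txt"))
      out$conserved_segment <- path("conserved_segment.txt")
    })
  }

  matrices <- NULL
  if (!is.null(config$alignments)) {
    matrices <- stage("distance", {
      ms <- lapply(names(config$alignments), function(mk) {
        aln <- read_fasta(config$alignments[[mk]])
        d <- k2p_matrix(aln, marker = mk)
        out[[paste0("distances_", mk)]] <-
          write_distance_tsv(d, path(sprintf("distances_%s.tsv", mk)))
        d
      })
      stats::setNames(ms, names(config$alignments))
    })
  } else if (!is.null(config$distance_tsvs)) {
    matrices <- stage("distance",
                      lapply(config$distance_tsvs, read_distance_tsv))
  }

  if ("group" %in% config$stages && !is.null(matrices)) {
    stage("group", {
      grp <- delimit_species_groups(matrices, config$thresholds,
                                    config$grouping_rule)
      out$groups <- .write_json(grp$groups, path("groups.json"))
    })
  }
  if ("diversity" %in% config$stages && !is.null(config$alignments)) {
    stage("diversity", {
      res <- lapply(names(config$alignments), function(mk) {
        aln <- read_fasta(config$alignments[[mk]])
        vs <- variable_sites(aln)
        pi <- nucleotide_diversity(aln)
        if (nchar(aln[[1]]) >= config$window) {
          track <- sliding_window_pi(aln, config$window, config$step)
          out[[paste0("pi_track_", mk)]] <-
            .write_tsv(track, path(sprintf("pi_track_%s.tsv", mk)))
        }
        list(marker = mk, variable_sites = vs$count,
             considered_sites = vs$considered,
             variable_pct = vs$percent, pi = pi)
      })
      out$diversity <- .write_json(res, path("diversity.json"))
    })
  }

  produced <- as.list(out)
  produced <- produced[order(names(produced))]
  files <- unlist(produced, use.names = FALSE)
  manifest <- list(
    package = "mitotick",
    version = as.character(utils::packageVersion("mitotick")),
    seed = config$seed,
    stages = config$stages,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  .write_json(manifest, path("manifest.json"))
  produced$manifest <- path("manifest.json")
  invisible(produced)
}
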