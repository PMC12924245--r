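# Orchestration: ingest -> merge -> filter -> quality gate -> refine ->
# att -> annotate -> similarity/cluster -> crispr -> integration -> report.
# Every stage is an exported function; run_pipeline() wires them together
# for the common case and make_report() serializes the results.

#' Run the full prophage surveillance pipeline
#'
#' @param candidates Candidate calls: a data.frame in the normalized layout
#'   or a list of `list(path =, dialect =)` entries for
#'   [ingest_detector_table()].
#' @param genomes Named list of `genome_record`s (names = genome ids).
#'   Optional, but required for boundary refinement, att detection,
#'   similarity and integration analysis.
#' @param checkv Optional CheckV table ([ingest_checkv()] output or path).
#' @param reference_id Optional genome id of the prophage-free reference
#'   strain within `genomes` (enables refinement and integration stages).
#' @param arrays Optional list of `crispr_array` objects (enables the
#'   spacer matching stage against the final prophages).
#' @param config A [pw_config()].
#' @param strain_tags Named character vector genome_id -> strain tag.
#' @param out_dir Optional output directory; when given, [make_report()]
#'   is called on the results.
#' @return List of class `pw_run`: `candidates, merged, final, records,
#'   att_sites, similarity, clusters, crispr, integration, config`.
#' @export
run_pipeline <- function(candidates, genomes = NULL, checkv = NULL,
                         reference_id = NULL, arrays = NULL,
                         config = pw_config(), strain_tags = NULL,
                         out_dir = NULL) {
  if (!is.data.frame(candidates)) {
    candidates <- do.call(rbind, lapply(candidates, function(x)
      ingest_detector_table(x$path, x$dialect)))
  }
  if (is.character(checkv)) checkv <- ingest_checkv(checkv)
  cons <- call_consensus(candidates, checkv, config, strain_tags)
  final <- cons$final
  reference <- if (!is.null(reference_id) && !is.null(genomes))
    genomes[[reference_id]] else NULL

  att_sites <- list()
  if (!is.null(genomes) && nrow(final) > 0) {
    for (i in seq_len(nrow(final))) {
      g <- genomes[[final$genome_id[i]]]
      if (is.null(g)) next
      if (!is.null(reference) && final$genome_id[i] != reference_id) {
        ref <- refine_boundaries(final[i, ], g, reference, config)
        final$start[i] <- ref$start; final$end[i] <- ref$end
        final$refined <- final$refined %||% FALSE
        final$refined[i] <- TRUE
      }
      att_sites[[final$region_id[i]]] <-
        detect_att_sites(final[i, ], g, config)
    }
    att_yes <- vapply(final$region_id, function(id)
      !is.null(att_sites[[id]]), logical(1))
    final$att_present <- ifelse(att_yes, "yes", final$att_present)
  }

  records <- list()
  if (!is.null(genomes) && nrow(final) > 0) {
    lex <- load_lexicon()
    for (i in seq_len(nrow(final))) {
      g <- genomes[[final$genome_id[i]]]
      if (is.null(g) || nrow(g$features) == 0) next
      records[[final$region_id[i]]] <- annotate_prophage(final[i, ],
                                                         g$features, lex)
    }
  }

  similarity <- NULL; clusters <- NULL
  if (!is.null(genomes) && nrow(final) >= 2) {
    seqs <- lapply(seq_len(nrow(final)), function(i) {
      g <- genomes[[final$genome_id[i]]]
      if (is.null(g)) return(NULL)
      substr(g$sequence, final$start[i] + 1L, final$end[i])
    })
    names(seqs) <- final$region_id
    seqs <- seqs[!vapply(seqs, is.null, logical(1))]
    if (length(seqs) >= 2) {
      similarity <- similarity_matrix(seqs, config)
      clusters <- cluster_taxa(similarity$matrix,
                               config$species_threshold_pct,
                               config$genus_threshold_pct)
    }
  }

  crispr <- NULL
  if (!is.null(arrays) && length(arrays) > 0 && !is.null(genomes) &&
      nrow(final) > 0) {
    sp <- do.call(rbind, lapply(arrays, function(a) data.frame(
      spacer_id = sprintf("%s_s%d", a$array_id, seq_along(a$spacers) - 1L),
      seq = a$spacers, genome_id = a$genome_id, stringsAsFactors = FALSE)))
    phs <- data.frame(phage_id = final$region_id,
                      genome_id = final$genome_id,
                      sequence = vapply(seq_len(nrow(final)), function(i)
                        substr(genomes[[final$genome_id[i]]]$sequence,
                               final$start[i] + 1L, final$end[i]),
                        character(1)),
                      stringsAsFactors = FALSE)
    m <- match_spacers(sp, phs, config)
    crispr <- estimate_fdr(m, sp, phs, config)
    if (length(arrays) >= 2) {
      crispr$shared <- find_shared_spacer_blocks(arrays)
    }
  }

  integration <- NULL
  if (!is.null(reference) && nrow(reference$features) > 0 &&
      nrow(final) > 0 && !is.null(genomes)) {
    per_genome <- lapply(split(final, final$genome_id), function(fg) {
      g <- genomes[[fg$genome_id[1]]]
      if (is.null(g) || nrow(g$features) == 0) return(NULL)
      integration_report(fg, g$features, reference$features, config)
    })
    per_genome <- per_genome[!vapply(per_genome, is.null, logical(1))]
    if (length(per_genome)) {
      integration <- list(
        summary = do.call(rbind, c(lapply(per_genome, `[[`, "summary"),
                                   make.row.names = FALSE)),
        detail = do.call(rbind, c(lapply(per_genome, `[[`, "detail"),
                                  make.row.names = FALSE)))
    }
  }

  res <- structure(list(candidates = candidates, merged = cons$merged,
                        final = final, records = records,
                        att_sites = att_sites, similarity = similarity,
                        clusters = clusters, crispr = crispr,
                        integration = integration, config = config),
                   class = "pw_run")
  if (!is.null(out_dir)) make_report(res, out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pw_run <- function(x, ...) {
  cat(sprintf("<pw_run> %d candidates -> %d merged -> %d final prophages\n",
              nrow(x$candidates), nrow(x$merged), nrow(x$final)))
  invisible(x)
}

#' Serialize pipeline results to a report directory
#'
#' Writes the per-prophage report TSV (region name, position, length in kb,
#' protein counts, completeness, quality, morphology, inducibility), BED
#' and GFF3 region tracks, a per-genome summary, the similarity matrix and
#' cluster memberships, the CRISPR match table and the integration table,
#' plus a JSON run manifest with the configuration snapshot, per-stage
#' record counts and output digests.
#'
#' @param res A `pw_run` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
make_report <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- function(f) file.path(out_dir, f)

  final <- res$final
  if (nrow(final) > 0 && length(res$records)) {
    final$morphology <- vapply(final$region_id, function(id) {
      r <- res$records[[id]]
      if (is.null(r)) NA_character_ else r$morphology
    }, character(1))
    final$inducibility <- vapply(final$region_id, function(id) {
      r <- res$records[[id]]
      if (is.null(r)) NA_character_ else r$inducibility$status
    }, character(1))
  }
  write_regions(final, p("prophages.tsv"), "tsv")
  if (any(c("morphology", "inducibility") %in% names(final))) {
    extra <- utils::read.delim(p("prophages.tsv"), stringsAsFactors = FALSE)
    extra$morphology <- final$morphology
    extra$inducibility <- final$inducibility
    utils::write.table(extra, p("prophages.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_regions(final, p("prophages.bed"), "bed")
  write_regions(final, p("prophages.gff3"), "gff3")
  paths <- c(paths, p("prophages.tsv"), p("prophages.bed"), p("prophages.gff3"))

  per_gen <- if (nrow(final) > 0) {
    do.call(rbind, lapply(split(final, final$genome_id), function(fg)
      data.frame(genome_id = fg$genome_id[1], n_regions = nrow(fg),
                 stringsAsFactors = FALSE)))
  } else data.frame(genome_id = character(0), n_regions = integer(0))
  utils::write.table(per_gen, p("genome_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, p("genome_summary.tsv"))

  if (!is.null(res$similarity)) {
    utils::write.table(res$similarity$entries, p("similarity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$clusters, p("clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p("similarity.tsv"), p("clusters.tsv"))
  }
  if (!is.null(res$crispr)) {
    utils::write.table(res$crispr$matches, p("spacer_matches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p("spacer_matches.tsv"))
  }
  if (!is.null(res$integration)) {
    utils::write.table(res$integration$summary, p("integration.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p("integration.tsv"))
  }

  manifest <- list(
    config = unclass(res$config),
    counts = list(candidates = nrow(res$candidates),
                  merged = nrow(res$merged), final = nrow(res$final)),
    outputs = as.list(tools::md5sum(paths)),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(paths, p("manifest.json")))
}
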