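# Consensus calling: merge multi-detector candidates, apply the five
# selection criteria and the quality gate, and emit the final set.
#
# Criteria, as applied by apply_filters():
#   (1) called by at least `min_detectors` detectors   [mandatory]
#   (2) length strictly exceeds `min_length_bp`        [mandatory]
#   (3) at least `min_phage_genes` phage-specific genes [mandatory]
#   (4) PHASTEST/VIBRANT raw score at or above that detector's run-wide
#       mean — enforced only when such a member exists (not_applicable
#       otherwise), since the two score scales are not commensurable
#   (5) att sites present — recorded as evidence; mandatory only in
#       strict_all mode, because att detection depends on boundary quality.

#' Merge candidate calls into consensus regions
#'
#' Overlapping candidates, and candidates separated by at most
#' `merge_gap_bp`, are merged into one region spanning their union. All
#' candidates must come from a single genome; callers group by genome.
#'
#' @param candidates Candidate data.frame from [ingest_detector_table()].
#' @param merge_gap_bp Maximum separation that still merges (default 3000).
#' @return Data.frame of consensus regions sorted by start, with columns
#'   `genome_id, start, end, n_detectors, detectors, phage_gene_count,
#'   total_gene_count, att_flag` and a list-column `members` holding each
#'   region's member candidate rows.
#' @export
merge_candidates <- function(candidates, merge_gap_bp = 3000L) {
  if (nrow(candidates) == 0) return(empty_consensus())
  if (length(unique(candidates$genome_id)) > 1) {
    stop("merge_candidates: candidates span multiple genomes; group first")
  }
  ir <- as_iranges(candidates)
  red <- IRanges::reduce(ir, min.gapwidth = merge_gap_bp + 1L)
  hit <- IRanges::findOverlaps(ir, red, maxgap = merge_gap_bp)
  grp <- rep(NA_integer_, nrow(candidates))
  grp[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  out <- lapply(seq_along(red), function(i) {
    mem <- candidates[which(grp == i), , drop = FALSE]
    data.frame(
      genome_id = mem$genome_id[1],
      start = min(mem$start), end = max(mem$end),
      n_detectors = length(unique(mem$detector)),
      detectors = paste(sort(unique(mem$detector)), collapse = ","),
      phage_gene_count = if (all(is.na(mem$phage_gene_count))) NA_integer_
      else max(mem$phage_gene_count, na.rm = TRUE),
      total_gene_count = if (all(is.na(mem$total_gene_count))) NA_integer_
      else max(mem$total_gene_count, na.rm = TRUE),
      att_flag = if (any(!is.na(mem$att_flag) & mem$att_flag)) TRUE
      else if (all(is.na(mem$att_flag))) NA else FALSE,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$members <- I(lapply(seq_along(red), function(i)
    candidates[which(grp == i), , drop = FALSE]))
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_consensus <- function() {
  res <- data.frame(genome_id = character(0), start = integer(0),
                    end = integer(0), n_detectors = integer(0),
                    detectors = character(0), phage_gene_count = integer(0),
                    total_gene_count = integer(0), att_flag = logical(0),
                    stringsAsFactors = FALSE)
  res$members <- I(list())
  res
}

#' Run-wide mean raw score per scoring detector
#'
#' The score criterion compares each member's raw score with the mean score
#' of all candidates of the same detector in the run (per-detector, because
#' PHASTEST and VIBRANT scores live on different scales).
#'
#' @param candidates All candidates of the run (across genomes).
#' @return Named numeric vector of means, one per detector with any score.
#' @export
detector_score_means <- function(candidates) {
  has <- !is.na(candidates$raw_score)
  if (!any(has)) return(stats::setNames(numeric(0), character(0)))
  tapply(candidates$raw_score[has], candidates$detector[has], mean)
}

#' Apply the selection criteria to one consensus region
#'
#' @param region One row of the output of [merge_candidates()] (with its
#'   `members` list-column).
#' @param config A [pw_config()].
#' @param score_means Run-wide per-detector score means from
#'   [detector_score_means()].
#' @param att_present Optional att evidence from the boundary module:
#'   `"yes"`, `"no"` or `"unknown"`. Defaults to the merged member flags.
#' @return One-row data.frame verdict: `multi_detector, length_ok,
#'   phage_genes_ok, score_ok, att_present, passed`.
#' @export
apply_filters <- function(region, config = pw_config(),
                          score_means = NULL, att_present = NULL) {
  mem <- region$members[[1]]
  multi <- region$n_detectors >= config$min_detectors
  len_ok <- (region$end - region$start) > config$min_length_bp
  genes_ok <- !is.na(region$phage_gene_count) &&
    region$phage_gene_count >= config$min_phage_genes
  scored <- mem[mem$detector %in% c("phastest", "vibrant") &
                  !is.na(mem$raw_score), , drop = FALSE]
  if (nrow(scored) == 0 || is.null(score_means) || length(score_means) == 0) {
    score_ok <- "not_applicable"
  } else {
    mu <- score_means[scored$detector]
    score_ok <- if (any(!is.na(mu) & scored$raw_score >= mu)) "pass" else "fail"
  }
  if (is.null(att_present)) {
    att_present <- if (is.na(region$att_flag)) "unknown"
    else if (region$att_flag) "yes" else "no"
  }
  passed <- multi && len_ok && genes_ok && score_ok != "fail"
  if (config$strict_all) {
    passed <- passed && score_ok == "pass" && att_present == "yes"
  }
  data.frame(multi_detector = multi, length_ok = len_ok,
             phage_genes_ok = genes_ok, score_ok = score_ok,
             att_present = att_present, passed = passed,
             stringsAsFactors = FALSE)
}

#' Finalize the prophage set: quality gate and region naming
#'
#' Retains verdict-passing regions whose CheckV tier is Medium, High or
#' Complete (the tier gate is skipped, with a warning, when no CheckV data
#' is supplied) and assigns region ids `strainTag-R1..Rn` ordered by
#' genomic start within each genome.
#'
#' @param regions Consensus regions (all genomes) with verdict columns bound
#'   (see [call_consensus()]), including `passed`.
#' @param checkv Optional data.frame from [ingest_checkv()]; matched on the
#'   provisional region id (`strainTag-Rn` computed over *passing* regions).
#' @param config A [pw_config()].
#' @param strain_tags Named character vector mapping genome_id to the short
#'   strain tag used in region ids; defaults to the genome_id itself.
#' @return Data.frame of final regions with `region_id`, completeness and
#'   quality columns.
#' @export
finalize_regions <- function(regions, checkv = NULL, config = pw_config(),
                             strain_tags = NULL) {
  keep <- regions[regions$passed, , drop = FALSE]
  if (nrow(keep) == 0) {
    keep$region_id <- character(0)
    keep$completeness_pct <- numeric(0)
    keep$quality_tier <- character(0)
    return(keep)
  }
  tag <- function(g) {
    if (!is.null(strain_tags) && g %in% names(strain_tags)) strain_tags[[g]] else g
  }
  # rows sorted by (genome, start); split() groups follow the same order,
  # so per-group ids unlist back into row order
  keep <- keep[order(keep$genome_id, keep$start), , drop = FALSE]
  keep$region_id <- unlist(lapply(split(keep$genome_id, keep$genome_id),
                                  function(g) paste0(tag(g[1]), "-R", seq_along(g))),
                           use.names = FALSE)
  if (!is.null(checkv) && nrow(checkv) > 0) {
    i <- match(keep$region_id, checkv$region_id)
    keep$completeness_pct <- checkv$completeness_pct[i]
    keep$quality_tier <- checkv$quality_tier[i]
    gate <- !is.na(keep$quality_tier) &
      keep$quality_tier %in% c("Medium", "High", "Complete")
    keep <- keep[gate, , drop = FALSE]
    # re-number after the gate so ids stay dense and start-ordered
    keep$region_id <- unlist(lapply(split(keep$genome_id, keep$genome_id),
                                    function(g) paste0(tag(g[1]), "-R", seq_along(g))),
                             use.names = FALSE)
  } else {
    warning("finalize_regions: no CheckV data; quality gate skipped")
    keep$completeness_pct <- NA_real_
    keep$quality_tier <- NA_character_
  }
  rownames(keep) <- NULL
  keep
}

#' Full consensus stage over a multi-genome candidate table
#'
#' Groups candidates by genome, merges, applies the criteria with run-wide
#' score means, and finalizes against CheckV data.
#'
#' @inheritParams finalize_regions
#' @param candidates Candidate data.frame (all genomes).
#' @return List with `merged` (all consensus regions + verdicts) and `final`
#'   (the retained set from [finalize_regions()]).
#' @export
call_consensus <- function(candidates, checkv = NULL, config = pw_config(),
                           strain_tags = NULL) {
  mus <- detector_score_means(candidates)
  merged <- do.call(rbind, lapply(split(candidates, candidates$genome_id),
                                  merge_candidates,
                                  merge_gap_bp = config$merge_gap_bp))
  if (is.null(merged) || nrow(merged) == 0) {
    merged <- empty_consensus()
    merged$multi_detector <- logical(0); merged$length_ok <- logical(0)
    merged$phage_genes_ok <- logical(0); merged$score_ok <- character(0)
    merged$att_present <- character(0); merged$passed <- logical(0)
    final <- suppressWarnings(finalize_regions(merged, checkv, config, strain_tags))
    return(list(merged = merged, final = final))
  }
  verd <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i)
    apply_filters(merged[i, , drop = FALSE], config, mus)))
  merged <- cbind(merged, verd)
  rownames(merged) <- NULL
  final <- suppressWarnings(finalize_regions(merged, checkv, config, strain_tags))
  if (is.null(checkv) || nrow(checkv) == 0) {
    warning("call_consensus: no CheckV data; quality gate skipped")
  }
  list(merged = merged, final = final)
}

#' Fraction of a genome covered by prophage, in percent
#'
#' Regions are merged before summing so overlaps are never double-counted.
#'
#' @param genome_length Genome length in bp (or a `genome_record`).
#' @param regions Data.frame with `start`/`end` internal coordinates.
#' @return Percentage in `[0, 100]`.
#' @export
prophage_fraction <- function(genome_length, regions) {
  if (inherits(genome_length, "genome_record")) {
    genome_length <- genome_length$length
  }
  if (genome_length <= 0) stop("prophage_fraction: zero-length genome")
  if (nrow(regions) == 0) return(0)
  cov <- sum(IRanges::width(IRanges::reduce(as_iranges(regions))))
  100 * cov / genome_length
}
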