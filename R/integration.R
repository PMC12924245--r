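# Integration-site integrity: does a prophage insertion disrupt host
# genes? Genes within the flank window of each refined boundary are
# compared with their homologues (same product string) in the syntenic
# locus of a prophage-free reference strain; absence or length change of a
# homologue is disruption evidence. Duplicate copies of a flanking gene
# product elsewhere in the genome are counted, and tRNA/tmRNA adjacency is
# reported.

#' Genes flanking a prophage boundary
#'
#' Returns the genes whose interval intersects
#' `[boundary - window, boundary + window]` for each side of the region.
#' Hypothetical-protein genes are listed but flagged as excluded from the
#' homologue comparison. Distances are nearest-edge distances to the
#' boundary (0 for genes straddling it).
#'
#' @param region One-row data.frame with `start`/`end`.
#' @param features Host feature data.frame (internal coordinates).
#' @param flank_window_bp Window size (default 1000).
#' @return Data.frame of flank genes with `side` (`"left"`/`"right"`),
#'   `distance_bp`, `straddles_boundary` and `excluded` columns.
#' @export
flanking_genes <- function(region, features, flank_window_bp = 1000L) {
  # the prophage's own genes (fully inside the region) are not host flank
  # genes; host genes straddling a boundary are kept as disruption evidence
  features <- features[!(features$start >= region$start &
                           features$end <= region$end), , drop = FALSE]
  one_side <- function(boundary, side) {
    lo <- boundary - flank_window_bp
    hi <- boundary + flank_window_bp
    g <- features[features$start <= hi & features$end >= lo, , drop = FALSE]
    if (nrow(g) == 0) {
      g$side <- character(0); g$distance_bp <- integer(0)
      g$straddles_boundary <- logical(0); g$excluded <- logical(0)
      return(g)
    }
    g <- g[order(g$start), , drop = FALSE]
    g$side <- side
    g$distance_bp <- pmax(0L, pmax(g$start - boundary, boundary - g$end))
    g$straddles_boundary <- g$start < boundary & g$end > boundary
    g$excluded <- g$product == "" |
      tolower(g$product) == "hypothetical protein"
    g
  }
  out <- rbind(one_side(region$start, "left"), one_side(region$end, "right"))
  rownames(out) <- NULL
  out
}

#' Compare flank genes with homologues in a reference locus
#'
#' A homologue is a feature with the same product string inside the
#' syntenic reference locus. `length_preserved` is strict equality of gene
#' lengths (a `tolerance_bp` flag exists for annotation jitter, default 0).
#' A reference gene whose product is absent from the flank of the
#' prophage-bearing strain would be picked up by the caller as disruption
#' evidence; here each flank gene is checked for presence and length.
#'
#' @param flank_genes Output of [flanking_genes()] (one side or both).
#' @param reference_features Feature data.frame of the reference strain.
#' @param ref_locus Optional `c(start, end)` restricting the reference
#'   features to the syntenic locus; `NULL` uses all features.
#' @param tolerance_bp Allowed length difference (default 0 = strict).
#' @return The flank genes with `homologue_found`, `homologue_length`,
#'   `length_preserved` (NA for excluded genes) added.
#' @export
compare_with_reference <- function(flank_genes, reference_features,
                                   ref_locus = NULL, tolerance_bp = 0L) {
  ref <- reference_features
  if (!is.null(ref_locus)) {
    ref <- ref[ref$start < ref_locus[2] & ref$end > ref_locus[1], ,
               drop = FALSE]
  }
  fg <- flank_genes
  fg$homologue_found <- rep(NA, nrow(fg))
  fg$homologue_length <- rep(NA_integer_, nrow(fg))
  fg$length_preserved <- rep(NA, nrow(fg))
  for (i in seq_len(nrow(fg))) {
    if (fg$excluded[i]) next
    hom <- ref[ref$product == fg$product[i], , drop = FALSE]
    fg$homologue_found[i] <- nrow(hom) > 0
    if (nrow(hom) > 0) {
      # nearest-length homologue resolves multi-copy products conservatively
      hlen <- hom$end - hom$start
      glen <- fg$end[i] - fg$start[i]
      fg$homologue_length[i] <- hlen[which.min(abs(hlen - glen))]
      fg$length_preserved[i] <- abs(fg$homologue_length[i] - glen) <= tolerance_bp
    } else {
      fg$length_preserved[i] <- FALSE
    }
  }
  fg
}

#' Count annotated copies of a gene product in a genome
#'
#' Exact product-string match over the whole annotation.
#'
#' @param product Product string (non-empty).
#' @param features Feature data.frame.
#' @return Integer copy count (0 when absent).
#' @export
count_gene_copies <- function(product, features) {
  if (is.na(product) || !nzchar(product)) {
    stop("count_gene_copies: empty product")
  }
  sum(features$product == product)
}

#' Classify a prophage integration site
#'
#' `intergenic` when no homologue check on either side shows absence or
#' length loss; `gene_disrupting` when some check does; `indeterminate`
#' when a side could not be compared (e.g. no syntenic locus resolvable)
#' and the other is clean. tRNA adjacency is TRUE when any tRNA/tmRNA
#' feature lies within the flank window.
#'
#' @param checked_flanks Output of [compare_with_reference()] covering both
#'   sides, or a list of per-side outputs.
#' @param indeterminate_sides Character vector of sides (`"left"`,
#'   `"right"`) whose reference comparison failed.
#' @return List with `classification`, `trna_adjacent` and `evidence` (the
#'   rows with disruption evidence).
#' @export
classify_integration <- function(checked_flanks, indeterminate_sides = character(0)) {
  if (is.list(checked_flanks) && !is.data.frame(checked_flanks)) {
    checked_flanks <- do.call(rbind, checked_flanks)
  }
  cf <- checked_flanks
  comp <- cf[!cf$excluded, , drop = FALSE]
  disrupted <- comp[!is.na(comp$length_preserved) & !comp$length_preserved, ,
                    drop = FALSE]
  classification <- if (nrow(disrupted) > 0) {
    "gene_disrupting"
  } else if (length(indeterminate_sides) > 0) {
    "indeterminate"
  } else {
    "intergenic"
  }
  trna <- any(cf$kind %in% c("tRNA", "tmRNA"))
  list(classification = classification, trna_adjacent = trna,
       evidence = disrupted)
}

#' Integration-site report for a set of prophages
#'
#' Convenience wrapper running [flanking_genes()],
#' [compare_with_reference()], [count_gene_copies()] and
#' [classify_integration()] per prophage, producing one report row per
#' prophage plus the per-gene detail table.
#'
#' @param regions Final region data.frame (with `region_id`).
#' @param features Host features (same genome as the regions).
#' @param reference_features Reference-strain features.
#' @param config A [pw_config()].
#' @return List with `summary` (per prophage: classification,
#'   trna_adjacent, n_flank_genes) and `detail` (per flank gene incl.
#'   `copies_in_host`).
#' @export
integration_report <- function(regions, features, reference_features,
                               config = pw_config()) {
  summaries <- list(); details <- list()
  for (i in seq_len(nrow(regions))) {
    fg <- flanking_genes(regions[i, ], features, config$flank_window_bp)
    ck <- compare_with_reference(fg, reference_features)
    cls <- classify_integration(ck)
    ck$copies_in_host <- vapply(seq_len(nrow(ck)), function(j) {
      if (ck$excluded[j]) NA_integer_
      else count_gene_copies(ck$product[j], features)
    }, integer(1))
    ck$region_id <- rep(regions$region_id[i], nrow(ck))
    summaries[[i]] <- data.frame(
      region_id = regions$region_id[i], classification = cls$classification,
      trna_adjacent = cls$trna_adjacent, n_flank_genes = nrow(fg),
      stringsAsFactors = FALSE)
    details[[i]] <- ck
  }
  list(summary = if (length(summaries)) do.call(rbind, summaries) else
    data.frame(region_id = character(0), classification = character(0),
               trna_adjacent = logical(0), n_flank_genes = integer(0)),
    detail = if (length(details)) do.call(rbind, details) else NULL)
}
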