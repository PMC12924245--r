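# VIRIDIC-style intergenomic similarity between prophage sequences and
# ICTV threshold clustering. The aligner is seed-and-extend: shared unique
# k-mer anchors are chained into collinear blocks (both strands) and the
# short gaps between consecutive exact runs are closed by global pairwise
# alignment, giving per-genome counts of identical aligned positions.
# similarity_pct = 100 * (identities_a + identities_b) / (len_a + len_b).

# Gaps larger than this (on either genome) are not aligned; their bases
# simply count as unaligned. Keeps the DP work bounded.
GAP_ALIGN_MAX <- 2000L

#' Pairwise intergenomic similarity of two sequences
#'
#' @param seq_a,seq_b DNA strings (or `genome_record`s).
#' @param config A [pw_config()]; `anchor_k` and `chain_gap_bp` control the
#'   seeding and chaining.
#' @return One-row data.frame: `len_a, len_b, identities_a, identities_b,
#'   aligned_frac_a, aligned_frac_b, length_ratio, similarity_pct`.
#' @export
pairwise_similarity <- function(seq_a, seq_b, config = pw_config()) {
  a <- if (inherits(seq_a, "genome_record")) seq_a$sequence else normalize_dna(seq_a)
  b <- if (inherits(seq_b, "genome_record")) seq_b$sequence else normalize_dna(seq_b)
  la <- nchar(a); lb <- nchar(b)
  if (la == 0 || lb == 0) stop("pairwise_similarity: empty sequence")
  out <- data.frame(len_a = la, len_b = lb, identities_a = 0, identities_b = 0,
                    aligned_frac_a = 0, aligned_frac_b = 0,
                    length_ratio = min(la, lb) / max(la, lb),
                    similarity_pct = 0)
  if (gsub("N", "", a) == "" || gsub("N", "", b) == "") {
    warning("pairwise_similarity: all-N sequence; similarity 0")
    return(out)
  }
  anc <- find_anchors(a, b, config$anchor_k)
  if (nrow(anc) == 0) return(out)
  chains <- chain_anchor_chains(anc, config$chain_gap_bp)
  ord <- order(vapply(chains, function(ch) ch$score, numeric(1)),
               decreasing = TRUE)
  used_a <- IRanges::IRanges(); used_b <- IRanges::IRanges()
  ident <- 0; cov_a <- 0; cov_b <- 0
  for (ch in chains[ord]) {
    u <- ch$runs[order(ch$runs$q_start), , drop = FALSE]
    span_a <- IRanges::IRanges(min(u$q_start) + 1L, max(u$q_end))
    bs <- min(u$r_start); be <- max(u$r_end)
    span_b <- IRanges::IRanges(bs + 1L, be)
    # one locus per genome: skip chains re-covering already aligned spans
    if (length(IRanges::findOverlaps(span_a, used_a)) > 0 ||
        length(IRanges::findOverlaps(span_b, used_b)) > 0) next
    used_a <- c(used_a, span_a); used_b <- c(used_b, span_b)
    res <- chain_identities(u, a, b, ch$strand)
    ident <- ident + res$ident
    cov_a <- cov_a + res$cov_a
    cov_b <- cov_b + res$cov_b
  }
  out$identities_a <- ident; out$identities_b <- ident
  out$aligned_frac_a <- min(1, cov_a / la)
  out$aligned_frac_b <- min(1, cov_b / lb)
  out$similarity_pct <- min(100, 100 * (2 * ident) / (la + lb))
  out
}

# Count identical positions along one chain: exact runs contribute their
# (overlap-trimmed) length; short inter-run gaps are closed by global
# alignment and contribute their matched positions.
chain_identities <- function(u, a, b, strand) {
  n <- nrow(u)
  ident <- 0; cov_a <- 0; cov_b <- 0
  last_q <- -Inf
  for (i in seq_len(n)) {
    contrib <- u$q_end[i] - max(u$q_start[i], last_q)
    contrib <- max(0, min(contrib, u$q_end[i] - u$q_start[i]))
    ident <- ident + contrib
    cov_a <- cov_a + contrib
    cov_b <- cov_b + contrib
    if (i < n) {
      qgap_s <- max(u$q_end[i], last_q)
      qgap <- u$q_start[i + 1L] - qgap_s
      bgap <- if (strand == "+") u$r_start[i + 1L] - u$r_end[i]
      else u$r_start[i] - u$r_end[i + 1L]
      if (qgap > 0 && bgap > 0 && qgap <= GAP_ALIGN_MAX && bgap <= GAP_ALIGN_MAX) {
        ga <- substr(a, qgap_s + 1L, u$q_start[i + 1L])
        gb <- if (strand == "+") substr(b, u$r_end[i] + 1L, u$r_start[i + 1L])
        else revcomp(substr(b, u$r_end[i + 1L] + 1L, u$r_start[i]))
        al <- Biostrings::pairwiseAlignment(ga, gb, type = "global")
        ident <- ident + Biostrings::nmatch(al)
        cov_a <- cov_a + qgap
        cov_b <- cov_b + bgap
      }
    }
    last_q <- max(last_q, u$q_end[i])
  }
  list(ident = ident, cov_a = cov_a, cov_b = cov_b)
}

#' All-pairs similarity matrix
#'
#' @param regions Named list of DNA strings (names are region ids), or a
#'   data.frame with `region_id` and `sequence` columns.
#' @param config A [pw_config()].
#' @return List with `entries` (one row per unordered pair) and `matrix`
#'   (symmetric percent similarity matrix, diagonal 100).
#' @export
similarity_matrix <- function(regions, config = pw_config()) {
  if (is.data.frame(regions)) {
    regions <- stats::setNames(as.list(regions$sequence), regions$region_id)
  }
  ids <- names(regions)
  if (anyDuplicated(ids)) stop("similarity_matrix: duplicate region ids")
  if (length(ids) < 2) stop("similarity_matrix: need at least 2 regions")
  m <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
  entries <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1L):length(ids)) {
      e <- pairwise_similarity(regions[[i]], regions[[j]], config)
      e <- cbind(data.frame(id_a = ids[i], id_b = ids[j],
                            stringsAsFactors = FALSE), e)
      entries[[length(entries) + 1L]] <- e
      m[i, j] <- m[j, i] <- e$similarity_pct
    }
  }
  list(entries = do.call(rbind, entries), matrix = m)
}

#' Cluster prophages at ICTV species and genus thresholds
#'
#' Single-linkage clustering of the similarity matrix, cut at the species
#' (default 95%) and genus (default 70%) demarcation thresholds. Pairs at
#' or above a threshold share a cluster at that level; the species
#' partition always refines the genus partition.
#'
#' @param sim_matrix Symmetric percent similarity matrix (diagonal 100).
#' @param species,genus Demarcation thresholds in percent.
#' @return Data.frame `region_id, species_cluster, genus_cluster` (integer
#'   cluster labels).
#' @export
cluster_taxa <- function(sim_matrix, species = 95, genus = 70) {
  ids <- rownames(sim_matrix)
  if (length(ids) == 1) {
    return(data.frame(region_id = ids, species_cluster = 1L,
                      genus_cluster = 1L, stringsAsFactors = FALSE))
  }
  d <- stats::as.dist(100 - sim_matrix)
  hc <- stats::hclust(d, method = "single")
  # merge everything strictly below the distance cut: sim >= thr  <=>
  # dist <= 100 - thr
  sp <- stats::cutree(hc, h = 100 - species)
  ge <- stats::cutree(hc, h = 100 - genus)
  data.frame(region_id = ids, species_cluster = as.integer(sp),
             genus_cluster = as.integer(ge), stringsAsFactors = FALSE)
}
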