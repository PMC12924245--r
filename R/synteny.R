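# Synteny anchoring and chaining: a lightweight anchor-and-chain aligner
# that localizes a prophage insertion by comparing the region (plus its
# extension window) against a phage-free reference strain. Anchors are
# k-mers unique in both sequences (both strands); chains are maximal
# collinear runs with bounded gaps. Precomputed whole-genome-aligner blocks
# can be ingested instead via read_xmfa().

#' Find synteny anchors between two sequences
#'
#' An anchor is a k-mer occurring exactly once in the query (counting both
#' strands) and exactly once in the reference (both strands), matched either
#' forward (`+`) or against the reference reverse strand (`-`). Positions
#' are 0-based starts on the forward strand of each sequence. k-mers
#' containing N never anchor.
#'
#' @param query,reference DNA strings.
#' @param k Anchor length (>= 11).
#' @return Data.frame `query_pos, ref_pos, length, strand`, ordered by
#'   `query_pos`.
#' @export
find_anchors <- function(query, reference, k = 21L) {
  if (k < 11L) stop("find_anchors: k must be >= 11")
  if (nchar(query) < k || nchar(reference) < k) {
    warning("find_anchors: k exceeds a sequence length")
    return(empty_anchors(k))
  }
  qk <- kmer_vector(query, k)
  rk <- kmer_vector(reference, k)
  qrc <- revcomp_many(qk)
  rrc <- revcomp_many(rk)
  # a word's occurrence count in a sequence includes reverse-strand hits
  dupq <- unique(c(qk, qrc)[duplicated(c(qk, qrc))])
  dupr <- unique(c(rk, rrc)[duplicated(c(rk, rrc))])
  okq <- !(qk %in% dupq) & !grepl("N", qk, fixed = TRUE)
  okr_pos <- !(rk %in% dupr) & !grepl("N", rk, fixed = TRUE)
  fwd <- match(qk, rk)
  rev <- match(qk, rrc)
  keep_f <- okq & !is.na(fwd) & okr_pos[ifelse(is.na(fwd), 1L, fwd)]
  keep_r <- okq & !is.na(rev) & okr_pos[ifelse(is.na(rev), 1L, rev)]
  anc <- rbind(
    data.frame(query_pos = which(keep_f) - 1L, ref_pos = fwd[keep_f] - 1L,
               length = rep(k, sum(keep_f)), strand = rep("+", sum(keep_f)),
               stringsAsFactors = FALSE),
    data.frame(query_pos = which(keep_r) - 1L, ref_pos = rev[keep_r] - 1L,
               length = rep(k, sum(keep_r)), strand = rep("-", sum(keep_r)),
               stringsAsFactors = FALSE))
  anc <- anc[order(anc$query_pos, anc$strand), , drop = FALSE]
  rownames(anc) <- NULL
  anc
}

empty_anchors <- function(k) {
  data.frame(query_pos = integer(0), ref_pos = integer(0),
             length = rep(k, 0), strand = character(0),
             stringsAsFactors = FALSE)
}

# Collapse diagonal runs of consecutive anchors into single units so the
# chaining DP stays small even when the sequences are near-identical.
collapse_runs <- function(anc) {
  if (nrow(anc) == 0) {
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      r_start = integer(0), r_end = integer(0),
                      strand = character(0), n_anchors = integer(0),
                      k = integer(0)))
  }
  out <- list()
  for (s in c("+", "-")) {
    a <- anc[anc$strand == s, , drop = FALSE]
    if (nrow(a) == 0) next
    a <- a[order(a$query_pos), , drop = FALSE]
    diag <- if (s == "+") a$query_pos - a$ref_pos else a$query_pos + a$ref_pos
    new_run <- c(TRUE, !(diff(a$query_pos) == 1L & diff(diag) == 0L))
    run <- cumsum(new_run)
    for (r in split(seq_len(nrow(a)), run)) {
      k <- a$length[r[1]]
      out[[length(out) + 1L]] <- data.frame(
        q_start = a$query_pos[r[1]], q_end = a$query_pos[r[length(r)]] + k,
        r_start = min(a$ref_pos[r]), r_end = max(a$ref_pos[r]) + k,
        strand = s, n_anchors = length(r), k = k, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$q_start), , drop = FALSE]
}

#' Chain anchors into collinear synteny blocks
#'
#' Per strand, a longest-increasing-subsequence-style dynamic programme
#' chains anchors that are collinear on both sequences with gaps of at most
#' `chain_gap_bp` between consecutive anchors. Blocks are extracted
#' greedily by score; each anchor lands in at most one block and blocks do
#' not overlap on the query.
#'
#' @param anchors Data.frame from [find_anchors()].
#' @param chain_gap_bp Maximum gap on either sequence (default 5000).
#' @return Data.frame of blocks: `q_start, q_end, r_start, r_end, strand,
#'   anchor_count, score` (score = anchors chained), ordered by `q_start`.
#' @export
chain_anchors <- function(anchors, chain_gap_bp = 5000L) {
  chains <- chain_anchor_chains(anchors, chain_gap_bp)
  if (length(chains) == 0) {
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      r_start = integer(0), r_end = integer(0),
                      strand = character(0), anchor_count = integer(0),
                      score = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, lapply(chains, function(ch) {
    cu <- ch$runs
    data.frame(q_start = min(cu$q_start), q_end = max(cu$q_end),
               r_start = min(cu$r_start), r_end = max(cu$r_end),
               strand = ch$strand, anchor_count = sum(cu$n_anchors),
               score = ch$score, stringsAsFactors = FALSE)
  }))
  res <- res[order(res$q_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Greedy chain decomposition over collapsed runs; returns each chain with
# its member runs so callers can count matched bases run by run.
chain_anchor_chains <- function(anchors, chain_gap_bp = 5000L) {
  runs <- collapse_runs(anchors)
  chains <- list()
  while (nrow(runs) > 0) {
    best <- NULL
    for (s in unique(runs$strand)) {
      u <- runs[runs$strand == s, , drop = FALSE]
      u <- u[order(u$q_start), , drop = FALSE]
      n <- nrow(u)
      score <- u$n_anchors
      prev <- rep(0L, n)
      for (i in seq_len(n)) {
        if (i == 1L) next
        for (j in seq_len(i - 1L)) {
          # adjacent runs may overlap by up to k-1 bp around an indel
          slack <- u$k[j] - 1L
          qgap <- u$q_start[i] - u$q_end[j]
          rgap <- if (s == "+") u$r_start[i] - u$r_end[j]
          else u$r_start[j] - u$r_end[i]
          ok <- qgap >= -slack && qgap <= chain_gap_bp &&
            rgap >= -slack && rgap <= chain_gap_bp
          if (ok && score[j] + u$n_anchors[i] > score[i]) {
            score[i] <- score[j] + u$n_anchors[i]
            prev[i] <- j
          }
        }
      }
      i <- which.max(score)
      chain <- integer(0)
      while (i > 0L) { chain <- c(i, chain); i <- prev[i] }
      cand <- list(score = max(score), rows = rownames(u)[chain],
                   runs = u[chain, , drop = FALSE], strand = s)
      if (is.null(best) || cand$score > best$score) best <- cand
    }
    chains[[length(chains) + 1L]] <- best
    qs <- min(best$runs$q_start); qe <- max(best$runs$q_end)
    drop <- rownames(runs) %in% best$rows |
      (runs$q_start < qe & runs$q_end > qs)  # query overlap with the block
    runs <- runs[!drop, , drop = FALSE]
  }
  chains
}

#' Refine prophage boundaries by synteny against a phage-free reference
#'
#' The called region, extended by `extension_bp` on both sides, is aligned
#' (anchor-and-chain) against the reference. The insertion shows up as a
#' query interval not covered by any synteny block; the refined left
#' boundary is the end of the last block before the insertion and the
#' refined right boundary the start of the first block after it. When no
#' flanking block exists on a side, the original boundary is kept with a
#' warning. The refined interval always stays within the extension window.
#'
#' @param region One-row data.frame with `start`/`end` (internal
#'   coordinates) on `host`.
#' @param host,reference `genome_record`s (or DNA strings).
#' @param config A [pw_config()].
#' @return The region row with `start`/`end` possibly updated and
#'   `refined = TRUE`.
#' @export
refine_boundaries <- function(region, host, reference, config = pw_config()) {
  hseq <- if (inherits(host, "genome_record")) host$sequence else host
  rseq <- if (inherits(reference, "genome_record")) reference$sequence else reference
  if (nchar(rseq) < config$anchor_k) {
    stop("refine_boundaries: reference shorter than anchor_k")
  }
  win_start <- max(0L, region$start - config$extension_bp)
  win_end <- min(nchar(hseq), region$end + config$extension_bp)
  window <- substr(hseq, win_start + 1L, win_end)
  anc <- find_anchors(window, rseq, config$anchor_k)
  blocks <- chain_anchors(anc, config$chain_gap_bp)
  region$refined <- TRUE
  if (nrow(blocks) == 0) {
    warning("refine_boundaries: no homology to reference; boundaries kept")
    return(region)
  }
  blocks$q_start <- blocks$q_start + win_start
  blocks$q_end <- blocks$q_end + win_start
  # candidate insertion gaps between consecutive blocks (plus the two open
  # ends of the window); pick the one overlapping the called region most
  bounds <- rbind(
    data.frame(gs = win_start, ge = blocks$q_start[1], left = NA, right = 1L),
    if (nrow(blocks) > 1) data.frame(
      gs = blocks$q_end[-nrow(blocks)], ge = blocks$q_start[-1],
      left = seq_len(nrow(blocks) - 1L), right = seq_len(nrow(blocks) - 1L) + 1L),
    data.frame(gs = blocks$q_end[nrow(blocks)], ge = win_end,
               left = nrow(blocks), right = NA))
  ov <- pmax(0, pmin(bounds$ge, region$end) - pmax(bounds$gs, region$start))
  if (all(ov <= 0)) {
    warning("refine_boundaries: no insertion gap overlaps the call; kept")
    return(region)
  }
  g <- bounds[which.max(ov), ]
  if (!is.na(g$left)) {
    region$start <- max(g$gs, region$start - config$extension_bp)
  } else {
    warning("refine_boundaries: no syntenic block left of the insertion")
  }
  if (!is.na(g$right)) {
    region$end <- min(g$ge, region$end + config$extension_bp)
  } else {
    warning("refine_boundaries: no syntenic block right of the insertion")
  }
  attr(region, "blocks") <- blocks
  region
}

#' Read precomputed whole-genome-alignment blocks (XMFA)
#'
#' Minimal reader for the XMFA dialect emitted by progressive whole-genome
#' aligners: per-entry headers `> seqid:start-end strand ...`, alignment
#' blocks separated by `=` lines. Returns block coordinate pairs (sequence
#' content is ignored); coordinates are converted to 0-based half-open.
#'
#' @param path Path to the XMFA file.
#' @return Data.frame `block, seqid, start, end, strand`.
#' @export
read_xmfa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  block <- 1L
  out <- list()
  for (ln in lines) {
    if (startsWith(ln, "=")) { block <- block + 1L; next }
    if (startsWith(ln, ">")) {
      m <- regmatches(ln, regexec("^>\\s*(\\S+):(\\d+)-(\\d+)\\s*([+-])", ln))[[1]]
      if (length(m) == 5) {
        out[[length(out) + 1L]] <- data.frame(
          block = block, seqid = m[2], start = as.integer(m[3]) - 1L,
          end = as.integer(m[4]), strand = m[5], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(block = integer(0), seqid = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
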