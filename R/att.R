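# attL/attR detection: the highest-scoring pair of direct repeats with one
# copy near each refined boundary. Seeds are exact shared words short
# enough that a repeat of att_min_len with att_max_mismatch mismatches
# still contains one; seeds are extended outward under the mismatch budget.

#' Detect attL/attR direct repeats around region boundaries
#'
#' Windows of `att_search_bp` centred on each boundary are searched for the
#' best pair of direct repeats: length at least `att_min_len`, at most
#' `att_max_mismatch` mismatches, same orientation, left copy upstream of
#' the right copy. Pairs are ranked by fewer mismatches first (the
#' recombination core of a genuine att pair is exact), then by longer
#' repeat, then by smaller left start. N mismatches everything.
#'
#' @param region One-row data.frame with `start`/`end` on `host`.
#' @param host A `genome_record` or DNA string.
#' @param config A [pw_config()].
#' @return `NULL` if no qualifying pair, else a list with `left_start,
#'   left_end, right_start, right_end` (host 0-based half-open),
#'   `repeat_seq` (left copy) and `mismatches`.
#' @export
detect_att_sites <- function(region, host, config = pw_config()) {
  hseq <- if (inherits(host, "genome_record")) host$sequence else host
  n <- nchar(hseq)
  half <- config$att_search_bp %/% 2L
  lw <- c(max(0L, region$start - half), min(n, region$start + half))
  rw <- c(max(0L, region$end - half), min(n, region$end + half))
  lseq <- substr(hseq, lw[1] + 1L, lw[2])
  rseq <- substr(hseq, rw[1] + 1L, rw[2])
  seed <- max(4L, config$att_min_len %/% (config$att_max_mismatch + 1L))
  if (nchar(lseq) < seed || nchar(rseq) < seed) return(NULL)
  lk <- kmer_vector(lseq, seed)
  rk <- kmer_vector(rseq, seed)
  shared <- intersect(lk[!grepl("N", lk, fixed = TRUE)],
                      rk[!grepl("N", rk, fixed = TRUE)])
  if (length(shared) == 0) return(NULL)
  lchar <- strsplit(lseq, "")[[1]]
  rchar <- strsplit(rseq, "")[[1]]
  lchar[lchar == "N"] <- "?"  # N never matches, not even another N
  rchar[rchar == "N"] <- "!"
  budget <- config$att_max_mismatch
  best <- NULL
  seen <- character(0)
  lpos_all <- split(seq_along(lk), lk)
  rpos_all <- split(seq_along(rk), rk)
  for (w in shared) {
    for (li in lpos_all[[w]]) for (ri in rpos_all[[w]]) {
      key <- paste0(li - ri)  # same diagonal pairs extend identically from
      # different seeds; still dedupe exact results below
      # extend: find, for each split of the budget, the maximal extents
      ext <- extend_repeat(lchar, rchar, li, ri, seed, budget)
      if (is.null(ext)) next
      len <- ext$len
      if (len < config$att_min_len) next
      cand_key <- paste(ext$lstart, len, sep = ":")
      if (cand_key %in% seen) next
      seen <- c(seen, cand_key)
      cand <- list(
        left_start = lw[1] + ext$lstart - 1L,
        left_end = lw[1] + ext$lstart - 1L + len,
        right_start = rw[1] + ext$rstart - 1L,
        right_end = rw[1] + ext$rstart - 1L + len,
        repeat_seq = substr(lseq, ext$lstart, ext$lstart + len - 1L),
        mismatches = ext$mm)
      blen <- if (is.null(best)) -1L else best$left_end - best$left_start
      if (is.null(best) ||
          cand$mismatches < best$mismatches ||
          (cand$mismatches == best$mismatches &&
             (len > blen ||
                (len == blen && cand$left_start < best$left_start)))) {
        best <- cand
      }
    }
  }
  if (!is.null(best) && best$right_start <= best$left_start) return(NULL)
  best
}

# Extend an exact seed (length `seed` at 1-based starts li/ri) outward,
# allowing at most `budget` mismatches in total, maximizing the repeat
# length; the repeat never starts or ends on a mismatch.
extend_repeat <- function(lchar, rchar, li, ri, seed, budget) {
  # walk right
  rext <- integer(budget + 1L)  # furthest matching extension for mm used
  mm <- 0L; last_ok <- 0L; step <- 0L
  repeat {
    step <- step + 1L
    lp <- li + seed - 1L + step; rp <- ri + seed - 1L + step
    if (lp > length(lchar) || rp > length(rchar)) break
    if (lchar[lp] == rchar[rp]) {
      last_ok <- step
      rext[mm + 1L] <- last_ok
    } else {
      mm <- mm + 1L
      if (mm > budget) break
    }
  }
  for (b in seq_len(budget)) rext[b + 1L] <- max(rext[b + 1L], rext[b])
  # walk left
  lext <- integer(budget + 1L)
  mm <- 0L; last_ok <- 0L; step <- 0L
  repeat {
    step <- step + 1L
    lp <- li - step; rp <- ri - step
    if (lp < 1L || rp < 1L) break
    if (lchar[lp] == rchar[rp]) {
      last_ok <- step
      lext[mm + 1L] <- last_ok
    } else {
      mm <- mm + 1L
      if (mm > budget) break
    }
  }
  for (b in seq_len(budget)) lext[b + 1L] <- max(lext[b + 1L], lext[b])
  best <- NULL
  for (bl in 0:budget) {
    br <- budget - bl
    len <- lext[bl + 1L] + seed + rext[br + 1L]
    # count actual mismatches inside the chosen extent
    l0 <- li - lext[bl + 1L]; r0 <- ri - lext[bl + 1L]
    idx <- seq_len(len) - 1L
    mmact <- sum(lchar[l0 + idx] != rchar[r0 + idx])
    if (is.null(best) || len > best$len ||
        (len == best$len && mmact < best$mm)) {
      best <- list(lstart = l0, rstart = r0, len = len, mm = mmact)
    }
  }
  best
}
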