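# CRISPR arrays, spacer orientation and recency, shared spacer blocks, and
# spacer-to-prophage matching with empirical target-decoy FDR control.
#
# Arrays are leader-polarized: spacer index 0 is leader-proximal, i.e. the
# most recently acquired. Spacer identity is always taken modulo reverse
# complement so orientation conventions never affect sharing.

#' Construct a CRISPR array object
#'
#' @param array_id,genome_id Identifiers (array ids combine strain and cas
#'   type, e.g. `"Bath_TypeIC"`).
#' @param spacers Character vector of spacer sequences ordered from the
#'   leader (index 0 = leader-proximal).
#' @param repeat_consensus Direct repeat consensus sequence.
#' @param cas_type One of `"I-E", "I-C", "I-F", "III-A", "none"`.
#' @param start,end Optional array interval on the genome (internal coords).
#' @param orientation_support `"predicted"`, `"block_corrected"` or
#'   `"unknown"`.
#' @return A list of class `crispr_array`.
#' @export
crispr_array <- function(array_id, genome_id, spacers, repeat_consensus = "",
                         cas_type = "none", start = NA_integer_,
                         end = NA_integer_,
                         orientation_support = "predicted") {
  spacers <- normalize_dna(spacers)
  if (length(spacers) < 1) stop("crispr_array: at least one spacer required")
  lens <- nchar(spacers)
  if (any(lens < 18 | lens > 50)) {
    stop("crispr_array: spacer lengths must lie in [18, 50]")
  }
  if (!cas_type %in% c("I-E", "I-C", "I-F", "III-A", "none")) {
    stop("crispr_array: unknown cas_type '", cas_type, "'")
  }
  structure(list(array_id = array_id, genome_id = genome_id,
                 spacers = spacers, repeat_consensus = repeat_consensus,
                 cas_type = cas_type, start = start, end = end,
                 orientation_support = orientation_support),
            class = "crispr_array")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("<crispr_array> %s (%s, cas %s): %d spacers, orientation %s\n",
              x$array_id, x$genome_id, x$cas_type, length(x$spacers),
              x$orientation_support))
  invisible(x)
}

#' Flip a CRISPR array's orientation
#'
#' Spacers are reverse-complemented and their order reversed; applying the
#' flip twice returns the original array.
#' @param array A `crispr_array`.
#' @return The flipped `crispr_array`.
#' @export
flip_array <- function(array) {
  array$spacers <- rev(revcomp_many(array$spacers))
  if (nzchar(array$repeat_consensus)) {
    array$repeat_consensus <- revcomp(array$repeat_consensus)
  }
  array
}

#' Ingest CRISPR arrays from a results file
#'
#' Two dialects: `"normalized_tsv"` (columns `array_id, genome_id, cas_type,
#' index, spacer_seq`, optional `repeat_consensus`, `orientation`) and
#' `"crisprcasfinder_json"` (the detector's result JSON:
#' `Sequences[].Crisprs[]` with `Regions[]` of type `Spacer`/`DR` and a
#' `Potential_Orientation`). Arrays predicted on the reverse strand are
#' stored leader-first: spacers reverse-complemented and order reversed.
#' Arrays with no adjacent cas genes are tagged `cas_type = "none"`; arrays
#' with zero spacers are skipped with a warning.
#'
#' @param path Path to the file.
#' @param dialect `"normalized_tsv"` or `"crisprcasfinder_json"`.
#' @return List of `crispr_array` objects.
#' @export
ingest_crispr_arrays <- function(path, dialect = c("normalized_tsv",
                                                   "crisprcasfinder_json")) {
  dialect <- match.arg(dialect)
  if (dialect == "normalized_tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("array_id", "genome_id", "cas_type", "index", "spacer_seq")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("ingest_crispr_arrays: missing columns ",
                           paste(miss, collapse = ", "))
    out <- lapply(split(tab, tab$array_id), function(a) {
      a <- a[order(a$index), , drop = FALSE]
      if (nrow(a) == 0 || all(!nzchar(a$spacer_seq))) {
        warning("ingest_crispr_arrays: array without spacers skipped")
        return(NULL)
      }
      rc <- if ("repeat_consensus" %in% names(a)) a$repeat_consensus[1] else ""
      arr <- crispr_array(a$array_id[1], a$genome_id[1], a$spacer_seq,
                          repeat_consensus = rc, cas_type = a$cas_type[1])
      if ("orientation" %in% names(a) && a$orientation[1] == "-") {
        arr <- flip_array(arr)
      }
      arr
    })
    out <- out[!vapply(out, is.null, logical(1))]
    names(out) <- NULL
    return(out)
  }
  js <- jsonlite::read_json(path)
  out <- list()
  for (sq in js$Sequences) {
    gid <- sq$Id
    for (cr in sq$Crisprs) {
      regions <- cr$Regions
      spacers <- unlist(lapply(regions, function(r)
        if (identical(r$Type, "Spacer")) r$Sequence else NULL))
      if (is.null(spacers) || length(spacers) == 0) {
        warning("ingest_crispr_arrays: array without spacers skipped")
        next
      }
      dr <- unlist(lapply(regions, function(r)
        if (identical(r$Type, "DR")) r$Sequence else NULL))
      cas <- if (!is.null(cr$CasType) && nzchar(cr$CasType)) cr$CasType else "none"
      arr <- crispr_array(
        if (!is.null(cr$Name)) cr$Name else paste0(gid, "_crispr", length(out) + 1),
        gid, spacers,
        repeat_consensus = if (length(dr)) dr[1] else "",
        cas_type = cas,
        start = if (!is.null(cr$Start)) as.integer(cr$Start) - 1L else NA_integer_,
        end = if (!is.null(cr$End)) as.integer(cr$End) else NA_integer_)
      if (identical(cr$Potential_Orientation, "-")) arr <- flip_array(arr)
      out[[length(out) + 1L]] <- arr
    }
  }
  out
}

#' Detect CRISPR arrays in a genome sequence
#'
#' Built-in fallback detector for synthetic data: finds three or more
#' tandem near-identical repeats (23-55 bp, at most 20% column disagreement
#' with the consensus) separated by unique 18-50 bp spacers. The leader is
#' provisionally assigned to the flank with the higher AT content within
#' 150 bp; `orientation_support` is `"predicted"`.
#'
#' @param genome A `genome_record` or DNA string.
#' @param min_repeats Minimum number of repeat copies (default 3).
#' @param seed_k Seed word length used to find repeat candidates.
#' @return List of `crispr_array` objects.
#' @export
detect_arrays <- function(genome, min_repeats = 3L, seed_k = 16L) {
  seq <- if (inherits(genome, "genome_record")) genome$sequence else genome
  gid <- if (inherits(genome, "genome_record")) genome$genome_id else "genome"
  n <- nchar(seq)
  if (n < seed_k * min_repeats) return(list())
  km <- kmer_vector(seq, seed_k)
  tab <- table(km)
  words <- names(tab)[tab >= min_repeats & tab <= 100]
  words <- words[!grepl("N", words, fixed = TRUE)]
  chars <- strsplit(seq, "")[[1]]
  taken <- IRanges::IRanges()
  out <- list()
  for (w in words) {
    pos <- which(km == w)  # 1-based starts
    # maximal runs of occurrences with CRISPR-like periodicity
    runs <- split(pos, cumsum(c(TRUE, !(diff(pos) >= 41 & diff(pos) <= 105))))
    for (p in runs) {
      if (length(p) < min_repeats) next
      span <- IRanges::IRanges(min(p), max(p) + seed_k - 1L)
      if (length(IRanges::findOverlaps(span, taken)) > 0) next
      arr <- build_array_from_seeds(chars, p, seed_k, n)
      if (is.null(arr)) next
      taken <- c(taken, span)
      arr_obj <- tryCatch(
        crispr_array(sprintf("%s_array%d", gid, length(out) + 1L), gid,
                     arr$spacers, repeat_consensus = arr$repeat_consensus,
                     start = arr$start, end = arr$end),
        error = function(e) NULL)
      if (is.null(arr_obj)) next
      if (!arr$leader_left) arr_obj <- flip_array(arr_obj)
      out[[length(out) + 1L]] <- arr_obj
    }
  }
  out
}

# Extend seed occurrences into the full repeat, cut out spacers, and pick
# the leader side. `p` holds 1-based seed starts.
build_array_from_seeds <- function(chars, p, seed_k, n) {
  m <- length(p)
  consensus_ok <- function(offsets) {
    col <- chars[offsets]
    mean(col == names(which.max(table(col)))) >= 0.8
  }
  # maximum extension that keeps repeats shorter than the smallest period
  # minus the minimum spacer length
  max_len <- min(55L, min(diff(p)) - 18L)
  lext <- 0L
  while (seed_k + lext < max_len && min(p) - lext - 1L >= 1L &&
         consensus_ok(p - lext - 1L)) lext <- lext + 1L
  rext <- 0L
  while (seed_k + lext + rext < max_len && max(p) + seed_k + rext <= n &&
         consensus_ok(p + seed_k + rext)) rext <- rext + 1L
  rep_len <- seed_k + lext + rext
  if (rep_len < 23L) return(NULL)
  starts <- p - lext          # 1-based repeat starts
  ends <- starts + rep_len - 1L
  sp_start <- ends[-m] + 1L
  sp_end <- starts[-1L] - 1L
  sp_len <- sp_end - sp_start + 1L
  if (any(sp_len < 18L | sp_len > 50L)) return(NULL)
  spacers <- substring(paste(chars, collapse = ""), sp_start, sp_end)
  cons <- paste(vapply(seq_len(rep_len), function(i) {
    col <- chars[starts + i - 1L]
    names(which.max(table(col)))
  }, character(1)), collapse = "")
  fl <- max(1L, starts[1] - 150L)
  fr <- min(n, ends[m] + 150L)
  at <- function(x) if (length(x)) mean(x %in% c("A", "T")) else 0
  at_left <- at(chars[fl:max(fl, starts[1] - 1L)])
  at_right <- at(chars[min(fr, ends[m] + 1L):fr])
  list(spacers = spacers, repeat_consensus = cons,
       start = starts[1] - 1L, end = ends[m],
       leader_left = at_left >= at_right)
}

#' Shared spacer blocks between arrays
#'
#' Spacer identity is exact string equality after orientation normalization
#' (a spacer equals its reverse complement's canonical form). For every
#' array pair, maximal runs of consecutive shared spacers are reported as
#' blocks, in both co-linear and reversed orientation; per-pair counts of
#' distinct shared spacers are also returned.
#'
#' @param arrays List of `crispr_array` objects.
#' @param min_block_len Minimum run length reported (default 1).
#' @return List with `blocks` (`array_a, array_b, a_start, a_end, b_start,
#'   b_end, length, orientation`) and `pair_counts` (`array_a, array_b,
#'   shared`). Index ranges are 0-based spacer indices, inclusive.
#' @export
find_shared_spacer_blocks <- function(arrays, min_block_len = 1L) {
  if (length(arrays) < 2) stop("find_shared_spacer_blocks: need >= 2 arrays")
  canon <- lapply(arrays, function(a) canonical_seq(a$spacers))
  ids <- vapply(arrays, function(a) a$array_id, character(1))
  blocks <- list(); counts <- list()
  for (i in seq_along(arrays)[-length(arrays)]) {
    for (j in (i + 1L):length(arrays)) {
      ca <- canon[[i]]; cb <- canon[[j]]
      counts[[length(counts) + 1L]] <- data.frame(
        array_a = ids[i], array_b = ids[j],
        shared = length(intersect(ca, cb)), stringsAsFactors = FALSE)
      pairs <- which(outer(ca, cb, "=="), arr.ind = TRUE)
      if (nrow(pairs) == 0) next
      key <- paste(pairs[, 1], pairs[, 2])
      has <- function(a, b) paste(a, b) %in% key
      for (orient in c("colinear", "reversed")) {
        step <- if (orient == "colinear") 1L else -1L
        startp <- pairs[!has(pairs[, 1] - 1L, pairs[, 2] - step), , drop = FALSE]
        for (r in seq_len(nrow(startp))) {
          ai <- startp[r, 1]; bi <- startp[r, 2]; len <- 1L
          while (has(ai + len, bi + step * len)) len <- len + 1L
          if (len < min_block_len) next
          if (orient == "reversed" && len == 1L) next  # reported by colinear
          b0 <- if (orient == "colinear") bi else bi - len + 1L
          blocks[[length(blocks) + 1L]] <- data.frame(
            array_a = ids[i], array_b = ids[j],
            a_start = ai - 1L, a_end = ai + len - 2L,
            b_start = b0 - 1L, b_end = b0 + len - 2L,
            length = len, orientation = orient, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(blocks = if (length(blocks)) do.call(rbind, blocks) else
    data.frame(array_a = character(0), array_b = character(0),
               a_start = integer(0), a_end = integer(0),
               b_start = integer(0), b_end = integer(0),
               length = integer(0), orientation = character(0),
               stringsAsFactors = FALSE),
    pair_counts = do.call(rbind, counts))
}

#' Correct array orientation using shared ancestral blocks
#'
#' Shared blocks inherited from a common ancestor are expected at the
#' distal (leader-far) end. If a shared block sits at the predicted leader
#' end of the array, the predicted orientation is judged wrong and the
#' array is flipped (`orientation_support = "block_corrected"`); a block at
#' the distal end confirms the orientation. Blocks at both ends are
#' conflicting evidence: the array is returned unchanged with
#' `orientation_support = "unknown"` and a warning.
#'
#' @param array A `crispr_array`.
#' @param shared_blocks The `blocks` data.frame from
#'   [find_shared_spacer_blocks()].
#' @return The (possibly flipped) `crispr_array`.
#' @export
orient_array <- function(array, shared_blocks) {
  n <- length(array$spacers)
  mine_a <- shared_blocks[shared_blocks$array_a == array$array_id, , drop = FALSE]
  mine_b <- shared_blocks[shared_blocks$array_b == array$array_id, , drop = FALSE]
  lo <- c(mine_a$a_start, mine_b$b_start)
  hi <- c(mine_a$a_end, mine_b$b_end)
  if (length(lo) == 0) return(array)
  at_leader <- any(lo == 0L)
  at_distal <- any(hi == n - 1L)
  if (at_leader && at_distal) {
    warning("orient_array: shared blocks at both ends of '", array$array_id,
            "'; orientation unknown")
    array$orientation_support <- "unknown"
    return(array)
  }
  if (at_leader) {
    array <- flip_array(array)
    array$orientation_support <- "block_corrected"
  } else if (at_distal) {
    array$orientation_support <- "block_corrected"
  }
  array
}

#' Rank spacers by acquisition recency
#'
#' Rank 1 is the leader-proximal spacer (most recently acquired); ranks
#' increase towards the distal end. Arrays with unresolved orientation are
#' flagged low-confidence.
#'
#' @param array A `crispr_array` with orientation resolved.
#' @return Data.frame `index_from_leader, spacer, recency_rank,
#'   low_confidence`.
#' @export
rank_recency <- function(array) {
  n <- length(array$spacers)
  data.frame(index_from_leader = seq_len(n) - 1L, spacer = array$spacers,
             recency_rank = seq_len(n),
             low_confidence = array$orientation_support == "unknown",
             stringsAsFactors = FALSE)
}

#' Match spacers against prophage sequences
#'
#' Both strands of every phage are scanned for near-perfect spacer matches:
#' at most `max_mismatches` substitutions, indels permitted and charged at
#' the configured affine gap costs. Each qualifying hit is scored
#' `matches x match_reward - mismatches x mismatch_penalty -
#' sum(gap_open + gap_extend x gap_length)`. All qualifying hits are
#' reported; a spacer may hit several phages. Spacers shorter than 18 nt
#' are skipped with a warning.
#'
#' @param spacers Data.frame with columns `spacer_id`, `seq` and optionally
#'   `genome_id` (the array's host genome), or a character vector.
#' @param phages Named list of DNA strings (names are phage ids), or a
#'   data.frame with `phage_id`, `sequence` and optionally `genome_id`.
#' @param config A [pw_config()].
#' @return Data.frame `spacer_id, phage_id, phage_pos, strand, matches,
#'   mismatches, gaps, gap_bases, score, self_exact` (one row per hit;
#'   `phage_pos` is the 0-based start on the phage forward strand).
#' @export
match_spacers <- function(spacers, phages, config = pw_config()) {
  if (is.character(spacers)) {
    spacers <- data.frame(spacer_id = paste0("sp", seq_along(spacers)),
                          seq = spacers, stringsAsFactors = FALSE)
  }
  if (is.data.frame(phages)) {
    ph_genomes <- if ("genome_id" %in% names(phages))
      stats::setNames(phages$genome_id, phages$phage_id) else NULL
    phages <- stats::setNames(as.list(phages$sequence), phages$phage_id)
  } else ph_genomes <- NULL
  subj <- Biostrings::DNAStringSet(unlist(phages))
  hits <- list()
  for (si in seq_len(nrow(spacers))) {
    sp <- normalize_dna(spacers$seq[si])
    if (nchar(sp) < 18) {
      warning("match_spacers: spacer '", spacers$spacer_id[si],
              "' shorter than 18 nt skipped")
      next
    }
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") sp else revcomp(sp)
      for (pi in seq_along(subj)) {
        mh <- Biostrings::matchPattern(pat, subj[[pi]],
                                       max.mismatch = config$max_mismatches,
                                       with.indels = TRUE)
        if (length(mh) == 0) next
        for (h in seq_along(mh)) {
          window <- as.character(mh[[h]])
          al <- Biostrings::pairwiseAlignment(
            pat, window, type = "global",
            substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
              match = config$match_reward, mismatch = -config$mismatch_penalty),
            gapOpening = config$gap_open, gapExtension = config$gap_extend)
          m <- Biostrings::nmatch(al)
          mm <- Biostrings::nmismatch(al)
          ind <- Biostrings::nindel(al)
          ngaps <- sum(Biostrings::insertion(ind)[, "Length"]) +
            sum(Biostrings::deletion(ind)[, "Length"])
          gapb <- sum(Biostrings::insertion(ind)[, "WidthSum"]) +
            sum(Biostrings::deletion(ind)[, "WidthSum"])
          if (mm > config$max_mismatches) next
          score <- m * config$match_reward - mm * config$mismatch_penalty -
            ngaps * config$gap_open - gapb * config$gap_extend
          self <- FALSE
          if (!is.null(ph_genomes) && "genome_id" %in% names(spacers)) {
            self <- mm == 0 && gapb == 0 &&
              identical(spacers$genome_id[si],
                        unname(ph_genomes[names(phages)[pi]]))
          }
          hits[[length(hits) + 1L]] <- data.frame(
            spacer_id = spacers$spacer_id[si], phage_id = names(phages)[pi],
            phage_pos = Biostrings::start(mh)[h] - 1L, strand = strand,
            matches = m, mismatches = mm, gaps = ngaps, gap_bases = gapb,
            score = score, self_exact = self, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(spacer_id = character(0), phage_id = character(0),
                      phage_pos = integer(0), strand = character(0),
                      matches = integer(0), mismatches = integer(0),
                      gaps = integer(0), gap_bases = integer(0),
                      score = numeric(0), self_exact = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Dinucleotide shuffle of a sequence
#'
#' Altschul-Erickson shuffle: a uniformly random sequence with exactly the
#' same dinucleotide (and hence mononucleotide) composition, generated via
#' a random Eulerian path in the dinucleotide multigraph.
#'
#' @param seq DNA string.
#' @return Shuffled DNA string of equal length and dinucleotide content.
#' @export
dinuc_shuffle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 4) return(seq)
  verts <- unique(ch)
  edges <- split(ch[-1], factor(ch[-n], levels = verts))
  last <- ch[n]
  if (length(verts) == 1) return(seq)
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last) return(NA_character_)
      e <- edges[[v]]
      e[sample.int(length(e), 1L)]
    }, character(1))
    # the chosen last edges must form paths that all reach `last`
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      seen <- character(0); cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  pools <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (v != last) {
      # remove one instance of the chosen last edge, shuffle, re-append it
      i <- match(last_edge[[v]], e)
      e <- e[-i]
      c(sample(e), last_edge[[v]])
    } else sample(e)
  })
  names(pools) <- verts
  used <- stats::setNames(integer(length(verts)), verts)
  out <- character(n)
  out[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:n) {
    used[cur] <- used[cur] + 1L
    nxt <- pools[[cur]][used[cur]]
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Empirical target-decoy FDR for spacer matches
#'
#' Decoy spacers are dinucleotide shuffles of each real spacer (seeded;
#' `n_decoy_sets` shuffles per spacer). For every score threshold s, the
#' FDR estimate is (decoy hits with score >= s, averaged per set) / (real
#' hits with score >= s); q-values are the monotonized minima over
#' admissible thresholds. Hits with q <= `fdr_alpha` are retained.
#'
#' @param matches Real matches from [match_spacers()].
#' @param spacers The spacer data.frame used for matching.
#' @param phages The phage set used for matching.
#' @param config A [pw_config()].
#' @param n_decoy_sets Decoy shuffles per spacer (default 10).
#' @param seed Seed for decoy generation; defaults to `config$rng_seed`.
#' @return List with `matches` (real matches + `q_value`), `retained`
#'   (subset with `q_value <= fdr_alpha`) and `decoy_hits` (count).
#' @export
estimate_fdr <- function(matches, spacers, phages, config = pw_config(),
                         n_decoy_sets = 10L, seed = NULL) {
  if (is.character(spacers)) {
    spacers <- data.frame(spacer_id = paste0("sp", seq_along(spacers)),
                          seq = spacers, stringsAsFactors = FALSE)
  }
  if (nrow(matches) == 0) {
    matches$q_value <- numeric(0)
    return(list(matches = matches, retained = matches, decoy_hits = 0L))
  }
  if (is.null(seed)) seed <- config$rng_seed
  decoys <- withr::with_seed(child_seed(seed, "decoys"), {
    do.call(rbind, lapply(seq_len(n_decoy_sets), function(s) {
      data.frame(spacer_id = paste0("decoy", s, "_", spacers$spacer_id),
                 seq = vapply(spacers$seq, dinuc_shuffle, character(1),
                              USE.NAMES = FALSE),
                 stringsAsFactors = FALSE)
    }))
  })
  dhits <- suppressWarnings(match_spacers(decoys, phages, config))
  thr <- sort(unique(matches$score), decreasing = TRUE)
  real_ge <- vapply(thr, function(s) sum(matches$score >= s), numeric(1))
  decoy_ge <- vapply(thr, function(s) sum(dhits$score >= s), numeric(1)) /
    n_decoy_sets
  fdr <- pmin(1, decoy_ge / real_ge)
  qv <- rev(cummin(rev(fdr)))  # min FDR over thresholds the hit survives
  matches$q_value <- qv[match(matches$score, thr)]
  retained <- matches[matches$q_value <= config$fdr_alpha, , drop = FALSE]
  list(matches = matches, retained = retained, decoy_hits = nrow(dhits))
}
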