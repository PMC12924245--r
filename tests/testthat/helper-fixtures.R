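# Shared helpers for building in-memory fixtures. Everything is seeded;
# no fixture is read from disk except the small packaged benchmark tables.

rdna <- function(n, gc = 0.5) phagewatch:::random_dna(n, gc)

rc <- function(x) phagewatch:::revcomp(x)

# substitute bases at a fixed per-base rate (never into the same base)
mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# one normalized candidate row
cand_row <- function(genome_id = "g", start, end, detector = "phigaro",
                     raw_score = NA_real_, phage = NA_integer_,
                     total = NA_integer_, att = NA) {
  data.frame(genome_id = genome_id, start = as.integer(start),
             end = as.integer(end), detector = detector,
             raw_score = raw_score,
             score_class = ifelse(is.na(raw_score), "missing", "unclassified"),
             phage_gene_count = as.integer(phage),
             total_gene_count = as.integer(total), att_flag = att,
             stringsAsFactors = FALSE)
}

# independent brute-force oracle for interval merging: paint covered
# positions, close gaps <= gap_bp between runs, read off the intervals
merge_oracle <- function(starts, ends, gap_bp, domain = max(ends) + gap_bp + 2L) {
  covered <- logical(domain)
  for (i in seq_along(starts)) covered[(starts[i] + 1L):ends[i]] <- TRUE
  r <- rle(covered)
  pos <- cumsum(r$lengths)
  # close inter-run gaps of size <= gap_bp
  if (length(r$lengths) > 2) {
    for (j in seq_along(r$values)) {
      if (!r$values[j] && j > 1 && j < length(r$values) &&
          r$lengths[j] <= gap_bp) {
        covered[(pos[j] - r$lengths[j] + 1L):pos[j]] <- TRUE
      }
    }
  }
  r <- rle(covered)
  ends2 <- cumsum(r$lengths)
  starts2 <- ends2 - r$lengths + 1L
  data.frame(start = starts2[r$values] - 1L, end = ends2[r$values])
}

# paths to the packaged benchmark tables
bench_path <- function(f) system.file("extdata", f, package = "phagewatch")

# first intergenic midpoint after min_pos with a comfortable margin, so a
# second implant never lands inside (or upstream of) an earlier one
intergenic_position <- function(genome, min_pos, margin = 300L) {
  f <- genome$features[order(genome$features$start), ]
  bounds <- c(0L, as.vector(rbind(f$start, f$end)), genome$length)
  gs <- bounds[seq(1, length(bounds), 2)]
  ge <- bounds[seq(2, length(bounds), 2)]
  for (i in seq_along(gs)) {
    lo <- max(gs[i], min_pos)
    if (ge[i] - lo > 2L * margin) return(as.integer(lo + margin))
  }
  stop("no intergenic gap after ", min_pos)
}
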