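# Plain-character DNA helpers shared across modules. Sequences are stored
# as uppercase character scalars over A/C/G/T/N; Biostrings objects are
# created at call sites that need matching or alignment.

normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Vectorized reverse complement for many short sequences (spacers).
revcomp_many <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Canonical form of a spacer: lexicographic min of sequence and its reverse
# complement, so identity checks are orientation-free.
canonical_seq <- function(x) {
  rc <- revcomp_many(x)
  ifelse(x <= rc, x, rc)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

gc_content <- function(x) {
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(x))
  sum(f[c("G", "C")]) / sum(f[c("A", "C", "G", "T")])
}

# All k-mers of a sequence as a character vector (length n-k+1), 1-based
# start positions implicit in the index. N-containing k-mers are marked so
# they never anchor (N mismatches everything).
kmer_vector <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}
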