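test_that("anchor finding matches a brute-force unique k-mer oracle", {
  set.seed(1)
  q <- rdna(100)
  anc <- find_anchors(q, q, 21L)
  # brute-force oracle: index every 21-mer of both strands, keep words seen
  # exactly once per sequence
  words <- substring(q, 1:80, 21:100)
  wrc <- vapply(words, rc, character(1), USE.NAMES = FALSE)
  cnt <- table(c(words, wrc))
  uniq <- names(cnt)[cnt == 1]
  expected <- which(words %in% uniq)
  expect_equal(anc$query_pos[anc$strand == "+"], expected - 1L)
  expect_equal(anc$ref_pos[anc$strand == "+"], expected - 1L)
  expect_equal(nrow(anc), length(expected))

  # reverse-complementing the reference flips every anchor to the - strand
  anc2 <- find_anchors(q, rc(q), 21L)
  expect_equal(sum(anc2$strand == "-"), nrow(anc))
  expect_equal(sum(anc2$strand == "+"), 0L)

  expect_equal(nrow(find_anchors(strrep("A", 100), strrep("A", 100), 21L)), 0L)
  expect_warning(find_anchors("ACGTACGTACGT", rdna(100), 21L), "exceeds")
  expect_error(find_anchors(rdna(50), rdna(50), 5L), ">= 11")
})

test_that("chaining produces collinear blocks with bounded gaps", {
  # perfectly collinear anchors form one block
  anc <- data.frame(query_pos = seq(0, 900, 100), ref_pos = seq(0, 900, 100),
                    length = 21L, strand = "+")
  b <- chain_anchors(anc)
  expect_equal(nrow(b), 1L)
  expect_equal(b$anchor_count, 10L)

  # two collinear groups separated by a 50-kb query gap split in two
  anc2 <- rbind(anc, within(anc, { query_pos <- query_pos + 50000L
                                   ref_pos <- ref_pos + 50000L }))
  b2 <- chain_anchors(anc2)
  expect_equal(nrow(b2), 2L)

  # exhaustive longest-chain oracle on a small random instance
  set.seed(3)
  n <- 12L
  anc3 <- data.frame(query_pos = sample.int(4000L, n),
                     ref_pos = sample.int(4000L, n),
                     length = 21L, strand = "+")
  best_len <- 0L
  for (m in 1:n) {
    combos <- utils::combn(n, m)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      idx <- idx[order(anc3$query_pos[idx])]
      q <- anc3$query_pos[idx]; r <- anc3$ref_pos[idx]
      if (m == 1L) { ok <- TRUE } else {
        # positions span < 5 kb, so the gap cap never binds: the oracle is
        # plain exhaustive LIS on both coordinates
        dq <- diff(q); dr <- diff(r)
        ok <- all(dq > 0) && all(dr > 0)
      }
      if (ok) best_len <- max(best_len, m)
    }
  }
  b3 <- chain_anchors(anc3)
  expect_equal(max(b3$anchor_count), best_len)
})

test_that("boundary refinement recovers implanted coordinates", {
  cfg <- pw_config()
  host <- make_host_genome(60000, 0.6, seed = 41)
  imp <- implant_prophage(host, phage_cassette(seed = 41), seed = 41)
  truth <- imp$truth

  # noiseless call: exact recovery
  reg <- data.frame(genome_id = "synth_host", start = truth$start,
                    end = truth$end)
  r <- refine_boundaries(reg, imp$genome, host, cfg)
  expect_equal(c(r$start, r$end), c(truth$start, truth$end))
  expect_true(r$refined)

  # detector call offset 4 kb into the flanks still recovers the truth
  off <- data.frame(genome_id = "synth_host", start = truth$start + 4000L,
                    end = truth$end + 4000L)
  r2 <- refine_boundaries(off, imp$genome, host, cfg)
  expect_lte(abs(r2$start - truth$start), cfg$anchor_k)
  expect_lte(abs(r2$end - truth$end), cfg$anchor_k)

  # refinement is idempotent on its own output
  r3 <- refine_boundaries(r, imp$genome, host, cfg)
  expect_equal(c(r3$start, r3$end), c(r$start, r$end))

  # refined interval always stays within the extension window
  expect_gte(r2$start, off$start - cfg$extension_bp)
  expect_lte(r2$end, off$end + cfg$extension_bp)

  # no homology: unchanged with a warning
  alien <- data.frame(genome_id = "x", start = 5000L, end = 18000L)
  expect_warning(r4 <- refine_boundaries(alien, rdna(30000), rdna(30000), cfg),
                 "no ")
  expect_equal(c(r4$start, r4$end), c(5000L, 18000L))
  expect_error(refine_boundaries(reg, imp$genome, "ACGT", cfg), "anchor_k")
})

test_that("att direct repeats are planted and recovered exactly", {
  cfg <- pw_config()
  set.seed(51)
  host <- make_host_genome(50000, 0.55, seed = 51)
  imp <- implant_prophage(host, phage_cassette(seed = 51), att_len = 15L,
                          seed = 51)
  truth <- imp$truth
  reg <- data.frame(start = truth$start, end = truth$end)
  att <- detect_att_sites(reg, imp$genome, cfg)
  expect_false(is.null(att))
  expect_equal(att$repeat_seq, truth$att_seq)
  expect_equal(att$mismatches, 0L)
  expect_equal(att$left_start, truth$start)
  expect_equal(att$right_end, truth$end)

  # reverse-complementing the host mirrors the pair
  L <- imp$genome$length
  rc_host <- rc(imp$genome$sequence)
  rc_reg <- data.frame(start = L - truth$end, end = L - truth$start)
  att_rc <- detect_att_sites(rc_reg, rc_host, cfg)
  expect_false(is.null(att_rc))
  expect_equal(att_rc$repeat_seq, rc(truth$att_seq))
  expect_equal(att_rc$left_start, L - truth$end)
  expect_equal(att_rc$right_end, L - truth$start)
})

test_that("att detection honours length threshold and tie-breaks", {
  cfg <- pw_config()
  set.seed(52)
  base <- rdna(12000)
  plant <- function(seq, repseq, at) {
    paste0(substr(seq, 1, at), repseq,
           substr(seq, at + nchar(repseq) + 1, nchar(seq)))
  }
  # a 10-bp repeat is below att_min_len = 11: the planted pair must never
  # be reported (a chance background repeat >= 11 bp may still exist)
  r10 <- rdna(10)
  h <- plant(plant(base, r10, 3000), r10, 9000)
  reg <- data.frame(start = 3000L, end = 9010L)
  res10 <- detect_att_sites(reg, h, cfg)
  if (!is.null(res10)) {
    expect_gte(res10$left_end - res10$left_start, cfg$att_min_len)
    expect_false(res10$left_start == 3000L && res10$right_start == 9000L)
  } else {
    expect_null(res10)
  }

  # competing 15-bp and 12-bp pairs: the longer pair wins (the reported
  # repeat may extend a little further into chance-matching context)
  r15 <- rdna(15); r12 <- rdna(12)
  h2 <- plant(plant(plant(plant(base, r15, 3000), r12, 3400), r15, 9000),
              r12, 9300)
  att <- detect_att_sites(data.frame(start = 3200L, end = 9100L), h2, cfg)
  expect_false(is.null(att))
  expect_gte(att$left_end - att$left_start, 15L)
  expect_true(grepl(r15, att$repeat_seq, fixed = TRUE) ||
                grepl(att$repeat_seq, r15, fixed = TRUE))
  expect_true(att$left_start <= 3000L && att$left_end >= 3015L)
})

test_that("XMFA alignment blocks are parsed with 0-based coordinates", {
  xmfa <- tempfile(fileext = ".xmfa")
  writeLines(c("> 1:101-200 + genomeA", "ACGT", "> 2:51-150 - genomeB",
               "ACGT", "=", "> 1:300-400 + genomeA", "GGTT", "="), xmfa)
  bl <- read_xmfa(xmfa)
  expect_equal(nrow(bl), 3L)
  expect_equal(bl$start[1], 100L)
  expect_equal(bl$end[1], 200L)
  expect_equal(bl$block, c(1L, 1L, 2L))
  expect_equal(bl$strand[2], "-")
})
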