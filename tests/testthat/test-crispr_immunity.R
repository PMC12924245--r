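cfg <- pw_config()

test_that("normalized TSV arrays ingest with orientation handling", {
  tsv <- tempfile(fileext = ".tsv")
  set.seed(20)
  sp <- replicate(4, rdna(30))
  df <- rbind(
    data.frame(array_id = "A1", genome_id = "g1", cas_type = "I-E",
               index = 0:3, spacer_seq = sp, orientation = "+"),
    data.frame(array_id = "A2", genome_id = "g2", cas_type = "none",
               index = 0:3, spacer_seq = sp, orientation = "-"))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  arrs <- ingest_crispr_arrays(tsv, "normalized_tsv")
  expect_length(arrs, 2L)
  a1 <- arrs[[which(vapply(arrs, `[[`, "", "array_id") == "A1")]]
  a2 <- arrs[[which(vapply(arrs, `[[`, "", "array_id") == "A2")]]
  expect_identical(a1$spacers, sp)
  expect_equal(a2$cas_type, "none")
  # reverse-orientation arrays come back reverse-complemented and reversed
  expect_identical(a2$spacers, rev(vapply(sp, rc, "", USE.NAMES = FALSE)))
})

test_that("CRISPRCasFinder-style JSON ingests with spacer-count fidelity", {
  set.seed(21)
  spacers69 <- replicate(69, rdna(32))
  regions <- list()
  for (i in seq_along(spacers69)) {
    regions[[length(regions) + 1]] <- list(Type = "DR",
                                           Sequence = "GTTTCAATCCACGCGCCCGT")
    regions[[length(regions) + 1]] <- list(Type = "Spacer",
                                           Sequence = spacers69[i])
  }
  js <- list(Sequences = list(list(Id = "Bath", Crisprs = list(
    list(Name = "Bath_TypeIC", Start = 1000, End = 5000, CasType = "I-C",
         Potential_Orientation = "+", Regions = regions),
    list(Name = "Bath_empty", Start = 9000, End = 9100,
         Potential_Orientation = "+",
         Regions = list(list(Type = "DR", Sequence = "GTTTCAATCC")))))))
  jf <- tempfile(fileext = ".json")
  jsonlite::write_json(js, jf, auto_unbox = TRUE)
  expect_warning(arrs <- ingest_crispr_arrays(jf, "crisprcasfinder_json"),
                 "without spacers")
  expect_length(arrs, 1L)
  expect_length(arrs[[1]]$spacers, 69L)
  expect_equal(arrs[[1]]$cas_type, "I-C")
})

test_that("planted arrays are detected with exact spacers; two repeats are not", {
  set.seed(22)
  bg <- rdna(30000)
  rep32 <- rdna(32)
  sp <- replicate(4, rdna(30))
  arrseq <- paste0(rep32, paste0(sp, rep32, collapse = ""))
  g <- paste0(substr(bg, 1, 12000), arrseq, substr(bg, 12001, 30000))
  found <- detect_arrays(g)
  expect_length(found, 1L)
  expect_length(found[[1]]$spacers, 4L)
  expect_setequal(phagewatch:::canonical_seq(found[[1]]$spacers),
                  phagewatch:::canonical_seq(sp))
  expect_equal(found[[1]]$orientation_support, "predicted")

  # two repeat copies only: below the tandem-repeat threshold
  two <- paste0(substr(bg, 1, 12000), rep32, sp[1], rep32,
                substr(bg, 12001, 30000))
  expect_length(detect_arrays(two), 0L)
  expect_length(detect_arrays(rdna(5000)), 0L)
})

test_that("shared spacer blocks are found modulo reverse complement", {
  set.seed(23)
  sp <- replicate(20, rdna(30))
  a1 <- crispr_array("A1", "g1", sp)
  # second array shares spacers 10..19 as its own indices 0..9
  a2 <- crispr_array("A2", "g2", c(sp[11:20], replicate(6, rdna(30))))
  sb <- find_shared_spacer_blocks(list(a1, a2))
  expect_equal(nrow(sb$blocks), 1L)
  expect_equal(sb$blocks$length, 10L)
  expect_equal(c(sb$blocks$a_start, sb$blocks$a_end), c(10L, 19L))
  expect_equal(sb$pair_counts$shared, 10L)

  # identical arrays share one block spanning everything
  sb2 <- find_shared_spacer_blocks(list(a1, crispr_array("A3", "g3", sp)))
  expect_equal(max(sb2$blocks$length), 20L)
  expect_equal(sb2$pair_counts$shared, 20L)

  # reverse-complementing one array leaves the blocks invariant
  sb3 <- find_shared_spacer_blocks(list(a1, flip_array(a2)))
  expect_equal(sort(sb3$blocks$length, decreasing = TRUE)[1], 10L)
  expect_equal(sb3$pair_counts$shared, sb$pair_counts$shared)
})

test_that("block-based orientation correction is an involution", {
  set.seed(24)
  sp <- replicate(12, rdna(30))
  anc <- replicate(5, rdna(30))
  # ancestral block at the distal end: orientation confirmed
  distal <- crispr_array("D", "g1", c(sp[1:7], anc))
  partner <- crispr_array("P", "g2", c(replicate(4, rdna(30)), anc))
  sb <- find_shared_spacer_blocks(list(distal, partner))
  o1 <- orient_array(distal, sb$blocks)
  expect_identical(o1$spacers, distal$spacers)
  expect_equal(o1$orientation_support, "block_corrected")

  # ancestral block at the leader end: array must flip
  leaderish <- crispr_array("L", "g3", c(anc, sp[1:7]))
  sb2 <- find_shared_spacer_blocks(list(leaderish, partner))
  o2 <- orient_array(leaderish, sb2$blocks)
  expect_identical(o2$spacers, flip_array(leaderish)$spacers)
  expect_equal(o2$orientation_support, "block_corrected")

  # flipping twice returns the original array
  expect_identical(flip_array(flip_array(leaderish))$spacers,
                   leaderish$spacers)

  # blocks at both ends: conflicting evidence
  both <- crispr_array("B", "g4", c(anc, sp[1:3], anc))
  sb3 <- find_shared_spacer_blocks(list(both, partner))
  expect_warning(o3 <- orient_array(both, sb3$blocks), "both ends")
  expect_equal(o3$orientation_support, "unknown")
})

test_that("recency ranks follow leader-proximal order", {
  set.seed(25)
  a <- crispr_array("A", "g", replicate(5, rdna(30)))
  rr <- rank_recency(a)
  expect_equal(rr$recency_rank, 1:5)
  expect_equal(rr$index_from_leader, 0:4)
  expect_false(any(rr$low_confidence))
  # flipped array ranks reverse relative to the original spacers
  rrf <- rank_recency(flip_array(a))
  expect_identical(rrf$spacer[1], rc(a$spacers[5]))
  # single spacer gets rank 1
  expect_equal(rank_recency(crispr_array("S", "g", rdna(30)))$recency_rank, 1L)
  u <- a; u$orientation_support <- "unknown"
  expect_true(all(rank_recency(u)$low_confidence))
})

test_that("spacer matching scores follow the stated cost scheme", {
  set.seed(26)
  phage <- rdna(5000)
  sp30 <- substr(phage, 2001, 2030)
  m <- match_spacers(sp30, list(phi = phage), cfg)
  expect_gte(nrow(m), 1L)
  best <- m[which.max(m$score), ]
  expect_equal(best$mismatches, 0L)
  expect_equal(best$score, 30L)  # 30 matches x reward 1
  expect_equal(best$phage_pos, 2000L)

  # one substitution: 29 matches - 1 mismatch = 28
  sub <- sp30
  substr(sub, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                 substr(sp30, 15, 15))[1]
  m2 <- match_spacers(sub, list(phi = phage), cfg)
  expect_equal(max(m2$score), 28L)
  expect_equal(m2$mismatches[which.max(m2$score)], 1L)

  # score identity holds for every emitted hit (recomputed independently)
  expect_true(all(m2$score == m2$matches * cfg$match_reward -
                    m2$mismatches * cfg$mismatch_penalty -
                    m2$gaps * cfg$gap_open - m2$gap_bases * cfg$gap_extend))

  # a random spacer has no near-perfect hit in an unrelated phage
  expect_equal(nrow(match_spacers(rdna(30), list(phi = rdna(50000)), cfg)), 0L)
  expect_warning(m3 <- match_spacers("ACGTACGTACGT", list(phi = phage), cfg),
                 "shorter than 18")
  expect_equal(nrow(m3), 0L)

  # reverse-strand protospacers are found with the - strand label
  mrc <- match_spacers(rc(sp30), list(phi = phage), cfg)
  expect_true(any(mrc$strand == "-" & mrc$mismatches == 0))
})

test_that("exact same-genome hits are flagged as potential self-targets", {
  set.seed(27)
  phage <- rdna(4000)
  sp <- data.frame(spacer_id = c("s1", "s2"),
                   seq = c(substr(phage, 101, 130), substr(phage, 501, 530)),
                   genome_id = c("gA", "gB"))
  ph <- data.frame(phage_id = "phi", sequence = phage, genome_id = "gA")
  m <- match_spacers(sp, ph, cfg)
  expect_true(m$self_exact[m$spacer_id == "s1" & m$mismatches == 0][1])
  expect_false(any(m$self_exact[m$spacer_id == "s2"]))
  # a near-identical (1-mismatch) spacer is not a self-target
  sp1 <- sp[1, ]; substr(sp1$seq, 10, 10) <- "N"
  sp1$seq <- gsub("N", setdiff(c("A","C","G","T"),
                               substr(phage, 110, 110))[1], sp1$seq)
  m1 <- match_spacers(sp1, ph, cfg)
  expect_false(any(m1$self_exact))
})

test_that("dinucleotide shuffling preserves composition and is seeded", {
  set.seed(28)
  for (i in 1:10) {
    s <- rdna(30)
    sh <- dinuc_shuffle(s)
    din <- function(x) sort(table(substring(x, 1:(nchar(x) - 1), 2:nchar(x))))
    expect_identical(din(s), din(sh))
    expect_equal(nchar(sh), nchar(s))
  }
  expect_identical(withr::with_seed(5, dinuc_shuffle(rdna(40))),
                   withr::with_seed(5, dinuc_shuffle(rdna(40))))
})

test_that("empirical FDR control behaves at the boundaries", {
  set.seed(29)
  phage <- rdna(8000)
  sp <- data.frame(spacer_id = c("t1", "t2"),
                   seq = c(substr(phage, 1001, 1030), substr(phage, 3001, 3030)))
  ph <- list(phi = phage)
  m <- match_spacers(sp, ph, cfg)
  fdr <- estimate_fdr(m, sp, ph, cfg, n_decoy_sets = 5L, seed = 29)
  # exact real hits and no decoy hits: q = 0 everywhere, all retained
  expect_true(all(fdr$matches$q_value == 0))
  expect_equal(nrow(fdr$retained), nrow(m))
  expect_true(all(fdr$matches$q_value >= 0 & fdr$matches$q_value <= 1))

  # zero real hits: empty retained set
  none <- match_spacers(data.frame(spacer_id = "x", seq = rdna(30)), ph, cfg)
  fdr0 <- estimate_fdr(none, data.frame(spacer_id = "x", seq = rdna(30)),
                       ph, cfg)
  expect_equal(nrow(fdr0$retained), 0L)
})
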