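test_that("overlapping and nearby candidates merge; distant ones do not", {
  cand <- rbind(cand_row(start = 100, end = 200, detector = "phigaro"),
                cand_row(start = 150, end = 300, detector = "phispy"))
  m <- merge_candidates(cand, 3000L)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100L, 300L))
  expect_equal(m$n_detectors, 2L)

  cand2 <- rbind(cand_row(start = 0, end = 10000),
                 cand_row(start = 14000, end = 20000, detector = "vibrant"))
  m2 <- merge_candidates(cand2, 3000L)  # gap 4000 > 3000
  expect_equal(nrow(m2), 2L)

  mixed <- rbind(cand_row("a", 0, 10), cand_row("b", 0, 10))
  expect_error(merge_candidates(mixed), "multiple genomes")
})

test_that("merging matches the brute-force position-set oracle and is idempotent", {
  set.seed(7)
  for (trial in 1:50) {
    n <- sample(3:50, 1)
    gap <- sample(c(5L, 20L, 100L), 1)
    starts <- sample.int(3000L, n)
    ends <- starts + sample.int(300L, n)
    cand <- do.call(rbind, lapply(seq_len(n), function(i)
      cand_row(start = starts[i], end = ends[i],
               detector = sample(c("phigaro", "phispy", "vibrant"), 1))))
    m <- merge_candidates(cand, gap)
    oracle <- merge_oracle(starts, ends, gap)
    expect_equal(m$start, oracle$start)
    expect_equal(m$end, oracle$end)
    # every candidate lands in exactly one region
    expect_equal(sum(vapply(m$members, nrow, integer(1))), n)
    # idempotence: re-merging the merged intervals changes nothing
    cand2 <- do.call(rbind, lapply(seq_len(nrow(m)), function(i)
      cand_row(start = m$start[i], end = m$end[i])))
    m2 <- merge_candidates(cand2, gap)
    expect_equal(m2$start, m$start)
    expect_equal(m2$end, m$end)
  }
})

test_that("the selection criteria behave as specified", {
  cfg <- pw_config()
  mk_region <- function(len, dets, phage, score = NA_real_,
                        scorer = "phastest") {
    rows <- do.call(rbind, lapply(seq_along(dets), function(i)
      cand_row(start = 0, end = len, detector = dets[i],
               raw_score = if (dets[i] %in% c("phastest", "vibrant")) score
               else NA_real_, phage = phage, total = phage + 10)))
    merge_candidates(rows, cfg$merge_gap_bp)
  }
  mus <- c(phastest = 100)

  # 9.5 kb, otherwise perfect: length criterion fails the region
  r <- mk_region(9500, c("phigaro", "phispy", "phastest"), 20, 150)
  v <- apply_filters(r, cfg, mus)
  expect_false(v$length_ok)
  expect_false(v$passed)

  # single detector, 15 kb, 12 phage genes: multi-detector criterion fails
  r <- mk_region(15000, "phigaro", 12)
  v <- apply_filters(r, cfg, mus)
  expect_false(v$multi_detector)
  expect_false(v$passed)

  # two detectors, no scoring member: score not applicable, region passes
  r <- mk_region(15000, c("phigaro", "phispy"), 12)
  v <- apply_filters(r, cfg, mus)
  expect_equal(v$score_ok, "not_applicable")
  expect_true(v$passed)

  # below-average score fails; at/above average passes
  r <- mk_region(15000, c("phigaro", "phastest"), 12, score = 50)
  expect_false(apply_filters(r, cfg, mus)$passed)
  r <- mk_region(15000, c("phigaro", "phastest"), 12, score = 100)
  expect_true(apply_filters(r, cfg, mus)$passed)
})

test_that("filter verdicts are monotone in the thresholds", {
  set.seed(11)
  cfg_hi <- pw_config()
  cfg_lo <- pw_config(min_detectors = 1L, min_length_bp = 5000L,
                      min_phage_genes = 5L)
  for (i in 1:60) {
    dets <- sample(c("phigaro", "phispy", "vibrant", "phastest"),
                   sample(1:3, 1))
    len <- sample(c(6000L, 9000L, 12000L, 20000L), 1)
    phage <- sample(c(4L, 9L, 12L, 20L), 1)
    rows <- do.call(rbind, lapply(dets, function(d)
      cand_row(start = 1000, end = 1000 + len, detector = d,
               raw_score = if (d %in% c("phastest", "vibrant")) 120 else NA,
               phage = phage, total = phage + 10L)))
    r <- merge_candidates(rows, 3000L)
    v_hi <- apply_filters(r, cfg_hi, c(phastest = 100, vibrant = 100))
    v_lo <- apply_filters(r, cfg_lo, c(phastest = 100, vibrant = 100))
    if (v_hi$passed) expect_true(v_lo$passed)
  }
})

test_that("finalize gates on quality tier and assigns start-ordered ids", {
  cand <- rbind(
    cand_row(start = 50000, end = 65000, detector = "phigaro", phage = 12, total = 30),
    cand_row(start = 50100, end = 64000, detector = "phispy", phage = 12, total = 30),
    cand_row(start = 5000, end = 17000, detector = "phigaro", phage = 15, total = 30),
    cand_row(start = 5100, end = 16500, detector = "vibrant", raw_score = 90,
             phage = 15, total = 30),
    cand_row(start = 90000, end = 102000, detector = "phispy", phage = 11, total = 28),
    cand_row(start = 90100, end = 101500, detector = "phigaro", phage = 11, total = 28))
  res <- suppressWarnings(call_consensus(cand))
  expect_equal(res$final$region_id, c("g-R1", "g-R2", "g-R3"))
  expect_true(all(diff(res$final$start) > 0))

  checkv <- data.frame(region_id = c("g-R1", "g-R2", "g-R3"),
                       completeness_pct = c(95, 20, 88),
                       quality_tier = c("High", "Low", "Medium"))
  res2 <- call_consensus(cand, checkv)
  expect_equal(nrow(res2$final), 2L)  # Low-tier region removed
  expect_equal(res2$final$region_id, c("g-R1", "g-R2"))

  expect_warning(call_consensus(cand), "quality gate skipped")
  # final set is always a subset of the merged set
  expect_true(all(res2$final$start %in% res$merged$start))
})

test_that("prophage fraction merges regions before summing", {
  expect_equal(prophage_fraction(10000, data.frame(start = 0L, end = 100L)), 1)
  two <- data.frame(start = c(0L, 50L), end = c(100L, 150L))  # 150 distinct bp
  expect_equal(prophage_fraction(10000, two), 1.5)
  expect_equal(prophage_fraction(10000, two[0, ]), 0)
  expect_error(prophage_fraction(0, two), "zero-length")
})

test_that("jitter-free synthetic detectors are recovered exactly", {
  host <- make_host_genome(120000, 0.6, seed = 21, genome_id = "hA")
  g <- host; truths <- list(); at <- 25000L
  for (k in 1:2) {
    pos <- intergenic_position(g, at)
    imp <- implant_prophage(g, phage_cassette(seed = 20 + k), position = pos,
                            seed = 30 + k, phage_id = paste0("phi", k))
    g <- imp$genome; truths[[k]] <- imp$truth
    at <- imp$truth$end + 10000L  # next implant well downstream
  }
  calls <- simulate_detector_calls(truths, "hA", g$length,
                                   detectors = c("phigaro", "phispy"),
                                   miss_rate = 0, fp_rate = 0,
                                   boundary_jitter_sd = 0, seed = 3)
  res <- suppressWarnings(call_consensus(calls))
  expect_equal(nrow(res$final), 2L)
  expect_equal(sort(res$final$start),
               sort(vapply(truths, `[[`, integer(1), "start")))
  expect_equal(sort(res$final$end),
               sort(vapply(truths, `[[`, integer(1), "end")))
})
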