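test_that("FASTA genomes are read, upper-cased and normalized", {
  fa <- tempfile(fileext = ".fasta")
  set.seed(1)
  writeLines(c(">chr1 test genome", tolower(rdna(1000))), fa)
  g <- read_genome(fa, "fasta")
  expect_equal(g$length, 1000L)
  expect_equal(g$genome_id, "chr1")
  expect_identical(g$sequence, toupper(g$sequence))

  writeLines(c(">x", "acgtrys"), fa)
  g2 <- read_genome(fa, "fasta")
  expect_identical(g2$sequence, "ACGTNNN")

  writeLines(">empty", fa)
  expect_error(read_genome(fa, "fasta"), "empty")
  expect_error(read_genome(tempfile(), "fasta"), "cannot read")
})

test_that("GenBank flat files yield sequence and typed features", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TESTGEN                 120 bp    DNA     linear   BCT",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             11..40",
    '                     /locus_tag="g1"',
    '                     /product="portal protein"',
    "     CDS             complement(45..74)",
    '                     /locus_tag="g2"',
    "     CDS             81..110",
    '                     /product="integrase"',
    "     tRNA            111..118",
    '                     /product="tRNA-Thr"',
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("ggttaaccgg", 6), collapse = " ")),
    "//"), gb)
  g <- read_genome(gb, "genbank")
  expect_equal(g$length, 120L)
  expect_equal(sum(g$features$kind == "CDS"), 3L)
  expect_equal(g$features$kind[4], "tRNA")
  # 1-based inclusive 11..40 becomes [10, 40)
  expect_equal(g$features$start[1], 10L)
  expect_equal(g$features$end[1], 40L)
  expect_equal(g$features$strand[2], "-")
  expect_equal(g$features$product[2], "")  # no product qualifier
  expect_equal(g$features$product[3], "integrase")
})

test_that("GFF3 coordinates convert to 0-based half-open and back", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tCDS\t11\t20\t.\t+\t0\tID=f1;product=portal protein",
    "chr1\ttest\tCDS\t31\t45\t.\t-\t0\tID=f2",
    "chr1\ttest\ttRNA\t50\t60\t.\t+\t.\tID=f3;product=tRNA-Phe"), gff)
  feats <- read_annotation(gff, "gff3")
  expect_equal(feats$start[1], 10L)
  expect_equal(feats$end[1], 20L)
  expect_equal(feats$product[2], "")
  expect_equal(feats$kind[3], "tRNA")
  # involution: internal -> 1-based -> internal
  back <- from_1based(feats$start + 1L, feats$end)
  expect_identical(back$start, feats$start)
  expect_identical(back$end, feats$end)
  expect_error(read_annotation(gff, "gff3", genome_length = 55L),
               "out of bounds")
})

test_that("detector tables ingest without dropping or inventing rows", {
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(genome_id = "g", start_1based = c(101, 5001),
                   end_1based = c(2100, 16000),
                   detector = c("phigaro", "vibrant"),
                   raw_score = c(NA, 88.2), phage_gene_count = c(4, 12),
                   total_gene_count = c(10, 30), att_flag = NA)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  cand <- ingest_detector_table(tsv)
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$start, c(100L, 5000L))
  expect_true(is.na(cand$raw_score[1]))  # missing stays missing
  expect_equal(cand$score_class, c("missing", "unclassified"))

  df$phage_gene_count[1] <- 99
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  expect_error(ingest_detector_table(tsv), "phage_gene_count")

  write.table(df[0, ], tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(cand0 <- ingest_detector_table(tsv), "empty")
  expect_equal(nrow(cand0), 0L)
  expect_error(ingest_detector_table(tsv, dialect = "nonsense"), "dialect")
})

test_that("CheckV ingestion maps tiers and validates completeness", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("region_id\tcompleteness\tquality",
               "Bath-R2\t100.0\tHigh-quality",
               "Bath-R1\t76.28\tMedium-quality",
               "X-R1\t12.4\tLow-quality",
               "Y-R1\t0\tNot-determined"), tsv)
  cv <- ingest_checkv(tsv)
  expect_equal(cv$quality_tier, c("High", "Medium", "Low", "NotDetermined"))
  expect_equal(cv$completeness_pct[1:2], c(100.0, 76.28))
  # absent region id is an explicit NA on lookup, never 0
  expect_true(is.na(cv$completeness_pct[match("Z-R9", cv$region_id)]))
  writeLines(c("region_id\tcompleteness\tquality", "A\t104\tHigh-quality"), tsv)
  expect_error(ingest_checkv(tsv), "completeness")
})

test_that("region writers honour the coordinate conventions", {
  reg <- data.frame(region_id = c("g-R1", "g-R2"), genome_id = "g",
                    start = c(100L, 0L), end = c(200L, 50L),
                    total_gene_count = c(10L, 5L),
                    phage_gene_count = c(8L, 3L),
                    completeness_pct = c(90, 50),
                    quality_tier = c("High", "Low"))
  bed <- tempfile(fileext = ".bed")
  write_regions(reg, bed, "bed")
  lines <- read.delim(bed, header = FALSE)
  expect_equal(lines$V2, c(100L, 0L))  # BED stays 0-based half-open
  expect_equal(lines$V3, c(200L, 50L))

  gff <- tempfile(fileext = ".gff3")
  write_regions(reg, gff, "gff3")
  g <- readLines(gff)
  expect_match(g[3], "\t1\t50\t")  # internal [0,50) -> GFF3 1..50

  tsv <- tempfile(fileext = ".tsv")
  write_regions(reg, tsv, "tsv")
  tab <- read.delim(tsv)
  expect_equal(tab$start_1based, c(101L, 1L))
  # round trip reproduces internal intervals exactly
  back <- read_regions_tsv(tsv)
  expect_identical(back$start, reg$start)
  expect_identical(back$end, reg$end)
})

test_that("printed kb lengths use half-up rounding to one decimal", {
  # a 71,406-bp interval prints as 71.4
  expect_identical(length_kb(1828592, 1899999 + 1899999 - 1899999), 71.4)
  expect_identical(length_kb(0, 71406), 71.4)
  expect_identical(length_kb(0, 29097), 29.1)
  expect_identical(length_kb(0, 10050), 10.1)  # half rounds up
})

test_that("interval validation enforces its invariants", {
  expect_error(genomic_interval("g", 10, 10), "start < end")
  expect_error(genomic_interval("g", -1, 5), ">= 0")
  expect_error(genomic_interval("g", 0, 10, genome_length = 5), "exceeds")
  gi <- genomic_interval("g", 0, 10, strand = "+")
  expect_equal(gi$end, 10L)
})
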