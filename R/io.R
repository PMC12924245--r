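# Readers and writers for the formats the pipeline consumes and emits.
# FASTA goes through Biostrings, GFF3 through rtracklayer; GenBank flat
# files are parsed by a small reader below (no offline GenBank parser is
# available as an R package dependency). All writers emitting coordinates
# for human consumption use the 1-based inclusive convention; BED is
# 0-based half-open as the format requires.

KIND_LEVELS <- c("CDS", "tRNA", "tmRNA", "repeat", "other")

#' Read a genome from FASTA or GenBank
#'
#' The sequence is upper-cased and any character outside A/C/G/T/N is mapped
#' to N. GenBank feature-table entries are imported as gene features.
#'
#' @param path Path to the file.
#' @param format `"fasta"` or `"genbank"`.
#' @param genome_id Identifier to assign; defaults to the record name.
#' @param strain Strain label (free text).
#' @return A `genome_record`: list with `genome_id`, `strain`, `sequence`,
#'   `length` and a `features` data.frame (feature_id, start, end, strand,
#'   kind, product) in internal 0-based half-open coordinates.
#' @export
read_genome <- function(path, format = c("fasta", "genbank"),
                        genome_id = NULL, strain = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_genome: cannot read '", path, "'")
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) == 0 || nchar(as.character(ss[[1]])) == 0) {
      stop("read_genome: empty sequence in '", path, "'")
    }
    seq <- normalize_dna(as.character(ss[[1]]))
    id <- if (is.null(genome_id)) sub("\\s.*$", "", names(ss)[1]) else genome_id
    feats <- empty_features()
  } else {
    gb <- parse_genbank(path)
    if (nchar(gb$sequence) == 0) stop("read_genome: empty sequence in '", path, "'")
    seq <- gb$sequence
    id <- if (is.null(genome_id)) gb$locus else genome_id
    feats <- gb$features
  }
  genome_record(id, strain, seq, feats)
}

#' Construct a genome record from parts
#' @param genome_id,strain Identifiers.
#' @param sequence DNA string (normalized to uppercase ACGTN).
#' @param features Feature data.frame as produced by [read_annotation()].
#' @return A list of class `genome_record`.
#' @export
genome_record <- function(genome_id, strain = "", sequence, features = NULL) {
  sequence <- normalize_dna(sequence)
  if (is.null(features)) features <- empty_features()
  len <- nchar(sequence)
  if (nrow(features) > 0) {
    bad <- features$start < 0 | features$end > len
    if (any(bad)) {
      stop("feature out of bounds: ", paste(features$feature_id[bad], collapse = ", "))
    }
  }
  structure(list(genome_id = as.character(genome_id), strain = strain,
                 sequence = sequence, length = len, features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s): %d bp, %d features\n",
              x$genome_id, x$strain, x$length, nrow(x$features)))
  invisible(x)
}

empty_features <- function() {
  data.frame(feature_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), kind = character(0), product = character(0),
             stringsAsFactors = FALSE)
}

#' Read gene annotations from GFF3 or GenBank
#'
#' GFF3 coordinates (1-based inclusive) are converted to internal 0-based
#' half-open coordinates; the `product` attribute is used when present, else
#' the product is the empty string.
#'
#' @param path Path to the file.
#' @param format `"gff3"` or `"genbank"`.
#' @param genome_length Optional genome length used to validate coordinates.
#' @return Feature data.frame (feature_id, start, end, strand, kind, product).
#' @export
read_annotation <- function(path, format = c("gff3", "genbank"),
                            genome_length = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_annotation: cannot read '", path, "'")
  if (format == "genbank") {
    feats <- parse_genbank(path)$features
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    kind <- as.character(gr$type)
    kind[kind == "repeat_region"] <- "repeat"
    kind[!kind %in% KIND_LEVELS] <- ifelse(
      kind[!kind %in% KIND_LEVELS] %in% c("gene", "mRNA"), "other", "other")
    product <- if ("product" %in% names(md)) as.character(md$product) else
      rep("", length(gr))
    product[is.na(product)] <- ""
    fid <- if ("ID" %in% names(md)) as.character(md$ID) else
      paste0("feat", seq_along(gr))
    fid[is.na(fid)] <- paste0("feat", which(is.na(fid)))
    feats <- data.frame(
      feature_id = fid,
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      kind = kind, product = product, stringsAsFactors = FALSE)
    feats$strand[feats$strand == "*"] <- "."
  }
  if (!is.null(genome_length) && nrow(feats) > 0) {
    bad <- feats$start < 0 | feats$end > genome_length
    if (any(bad)) {
      stop("read_annotation: feature out of bounds: ",
           paste(feats$feature_id[bad], collapse = ", "))
    }
  }
  feats
}

# --- minimal GenBank flat-file reader -------------------------------------
# Handles single-record files: LOCUS line, FEATURES table with simple
# 'start..end' / 'complement(start..end)' locations (join() collapsed to its
# envelope), /product and /locus_tag qualifiers, and the ORIGIN block.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- "genome"
  ll <- grep("^LOCUS", lines, value = TRUE)
  if (length(ll)) locus <- strsplit(trimws(sub("^LOCUS\\s+", "", ll[1])), "\\s+")[[1]][1]

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  feats <- empty_features()
  if (length(fstart)) {
    fend <- if (length(ostart)) ostart[1] - 1L else length(lines)
    flines <- lines[(fstart[1] + 1L):fend]
    # feature headers start at column 6, qualifiers at column 22
    hdr <- grepl("^ {5}\\S", flines)
    idx <- which(hdr)
    recs <- list()
    for (i in seq_along(idx)) {
      from <- idx[i]
      to <- if (i < length(idx)) idx[i + 1] - 1L else length(flines)
      chunk <- flines[from:to]
      key <- strsplit(trimws(chunk[1]), "\\s+")[[1]]
      type <- key[1]
      loc <- paste(key[-1], collapse = "")
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      if (length(nums) < 2) next
      qual <- paste(trimws(chunk[-1]), collapse = " ")
      product <- ""
      m <- regmatches(qual, regexpr('/product="[^"]*"', qual))
      if (length(m)) product <- sub('/product="', "", sub('"$', "", m))
      tag <- ""
      m <- regmatches(qual, regexpr('/locus_tag="[^"]*"', qual))
      if (length(m)) tag <- sub('/locus_tag="', "", sub('"$', "", m))
      kind <- switch(type, CDS = "CDS", tRNA = "tRNA", tmRNA = "tmRNA",
                     repeat_region = "repeat",
                     source = NA_character_, "other")
      if (is.na(kind)) next
      recs[[length(recs) + 1L]] <- data.frame(
        feature_id = if (nzchar(tag)) tag else paste0(type, "_", length(recs) + 1L),
        start = min(nums) - 1L, end = max(nums), strand = strand,
        kind = kind, product = product, stringsAsFactors = FALSE)
    }
    if (length(recs)) feats <- do.call(rbind, recs)
  }
  seq <- ""
  if (length(ostart)) {
    send <- grep("^//", lines)
    send <- if (length(send)) send[send > ostart[1]][1] - 1L else length(lines)
    body <- lines[(ostart[1] + 1L):send]
    seq <- normalize_dna(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }
  list(locus = locus, sequence = seq, features = feats)
}

# --- detector candidate tables --------------------------------------------

DETECTORS <- c("phastest", "phigaro", "vibrant", "phispy", "other")

#' Ingest a table of candidate prophage calls
#'
#' The normalized TSV dialect is the contract: tab-delimited with a header
#' row and columns `genome_id, start_1based, end_1based, detector, raw_score,
#' phage_gene_count, total_gene_count, att_flag`. Native detector dialects
#' are accepted as best-effort adapters that map onto the same columns.
#' Rows are never imputed: a missing score stays missing (`NA`).
#'
#' @param path Path to the table.
#' @param dialect One of `"normalized_tsv"`, `"phastest"`, `"phigaro"`,
#'   `"vibrant"`, `"phispy"`.
#' @return Data.frame of candidate regions with internal coordinates and
#'   columns `genome_id, start, end, detector, raw_score, score_class,
#'   phage_gene_count, total_gene_count, att_flag`.
#' @export
ingest_detector_table <- function(path, dialect = "normalized_tsv") {
  if (!dialect %in% c("normalized_tsv", DETECTORS[DETECTORS != "other"])) {
    stop("ingest_detector_table: unknown dialect '", dialect, "'")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0) {
    warning("ingest_detector_table: empty table '", path, "'")
    return(empty_candidates())
  }
  if (dialect == "normalized_tsv") {
    need <- c("genome_id", "start_1based", "end_1based", "detector")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("ingest_detector_table: missing columns ",
                           paste(miss, collapse = ", "))
    cand <- data.frame(
      genome_id = as.character(tab$genome_id),
      start = as.integer(tab$start_1based) - 1L,
      end = as.integer(tab$end_1based),
      detector = as.character(tab$detector),
      raw_score = if ("raw_score" %in% names(tab))
        suppressWarnings(as.numeric(tab$raw_score)) else NA_real_,
      phage_gene_count = if ("phage_gene_count" %in% names(tab))
        as.integer(tab$phage_gene_count) else NA_integer_,
      total_gene_count = if ("total_gene_count" %in% names(tab))
        as.integer(tab$total_gene_count) else NA_integer_,
      att_flag = if ("att_flag" %in% names(tab))
        as.logical(tab$att_flag) else NA,
      stringsAsFactors = FALSE)
  } else {
    # native adapters: expect at least genome/start/end columns under common
    # detector-specific names; everything is mapped onto the normalized set.
    lower <- tolower(names(tab))
    pick <- function(cands) {
      i <- which(lower %in% cands)[1]
      if (is.na(i)) NULL else tab[[i]]
    }
    g <- pick(c("genome", "genome_id", "scaffold", "contig", "accession"))
    s <- pick(c("start", "begin", "region_start", "nucleotide start"))
    e <- pick(c("end", "stop", "region_end", "nucleotide stop"))
    if (is.null(g) || is.null(s) || is.null(e)) {
      stop("ingest_detector_table: cannot map '", dialect, "' table columns")
    }
    sc <- pick(c("score", "completeness_score", "total_score"))
    pg <- pick(c("phage_genes", "phage_gene_count", "phage_gene_num"))
    tg <- pick(c("total_genes", "total_gene_count", "gene_num"))
    cand <- data.frame(
      genome_id = as.character(g), start = as.integer(s) - 1L,
      end = as.integer(e), detector = dialect,
      raw_score = if (is.null(sc)) NA_real_ else suppressWarnings(as.numeric(sc)),
      phage_gene_count = if (is.null(pg)) NA_integer_ else as.integer(pg),
      total_gene_count = if (is.null(tg)) NA_integer_ else as.integer(tg),
      att_flag = NA, stringsAsFactors = FALSE)
  }
  bad <- which(!cand$detector %in% DETECTORS)
  if (length(bad)) stop("ingest_detector_table: unknown detector in row(s) ",
                        paste(bad, collapse = ", "))
  bad <- which(cand$start < 0 | cand$start >= cand$end)
  if (length(bad)) stop("ingest_detector_table: invalid interval in row(s) ",
                        paste(bad, collapse = ", "))
  bad <- which(!is.na(cand$phage_gene_count) & !is.na(cand$total_gene_count) &
                 cand$phage_gene_count > cand$total_gene_count)
  if (length(bad)) stop("ingest_detector_table: phage_gene_count > ",
                        "total_gene_count in row(s) ", paste(bad, collapse = ", "))
  cand$score_class <- ifelse(is.na(cand$raw_score), "missing", "unclassified")
  cand[c("genome_id", "start", "end", "detector", "raw_score", "score_class",
         "phage_gene_count", "total_gene_count", "att_flag")]
}

empty_candidates <- function() {
  data.frame(genome_id = character(0), start = integer(0), end = integer(0),
             detector = character(0), raw_score = numeric(0),
             score_class = character(0), phage_gene_count = integer(0),
             total_gene_count = integer(0), att_flag = logical(0),
             stringsAsFactors = FALSE)
}

QUALITY_TIERS <- c("Complete", "High", "Medium", "Low", "NotDetermined")

#' Ingest a CheckV quality table
#'
#' Expects a TSV with columns `region_id`, `completeness` (percent) and
#' `quality` (e.g. `"High-quality"`, `"Complete"`, `"Not-determined"`).
#'
#' @param path Path to the TSV.
#' @return Data.frame with `region_id`, `completeness_pct`, `quality_tier`.
#' @export
ingest_checkv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "completeness", "quality")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("ingest_checkv: missing columns ",
                         paste(miss, collapse = ", "))
  comp <- as.numeric(tab$completeness)
  if (any(!is.na(comp) & (comp < 0 | comp > 100))) {
    stop("ingest_checkv: completeness outside [0, 100]")
  }
  tier <- vapply(tab$quality, function(q) {
    q <- tolower(q)
    if (grepl("complete", q)) "Complete"
    else if (grepl("high", q)) "High"
    else if (grepl("medium", q)) "Medium"
    else if (grepl("low", q)) "Low"
    else "NotDetermined"
  }, character(1), USE.NAMES = FALSE)
  data.frame(region_id = as.character(tab$region_id), completeness_pct = comp,
             quality_tier = tier, stringsAsFactors = FALSE)
}

#' Write consensus regions to BED, GFF3 or a report TSV
#'
#' BED output is 0-based half-open; GFF3 and the TSV report are 1-based
#' inclusive. The TSV mirrors the per-prophage report layout: region name,
#' position, length in kb to one decimal, total and phage protein counts,
#' completeness and quality tier.
#'
#' @param regions Consensus region data.frame (see [merge_candidates()]).
#' @param path Output path.
#' @param format `"bed"`, `"gff3"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, format = c("tsv", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- data.frame(regions$genome_id, regions$start, regions$end,
                      if ("region_id" %in% names(regions)) regions$region_id
                      else paste0("region", seq_len(nrow(regions))))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else if (format == "gff3") {
    con <- file(path, "w")
    writeLines("##gff-version 3", con)
    if (nrow(regions) > 0) {
      id <- if ("region_id" %in% names(regions)) regions$region_id
      else paste0("region", seq_len(nrow(regions)))
      writeLines(sprintf("%s\tphagewatch\tprophage\t%d\t%d\t.\t.\t.\tID=%s",
                         regions$genome_id, regions$start + 1L, regions$end,
                         id), con)
    }
    close(con)
  } else {
    out <- data.frame(
      region_id = if ("region_id" %in% names(regions)) regions$region_id
      else paste0("region", seq_len(nrow(regions))),
      genome_id = regions$genome_id,
      start_1based = regions$start + 1L,
      end_1based = regions$end,
      length_kb = sprintf("%.1f", length_kb(regions$start, regions$end)),
      total_proteins = if ("total_gene_count" %in% names(regions))
        regions$total_gene_count else NA_integer_,
      phage_proteins = if ("phage_gene_count" %in% names(regions))
        regions$phage_gene_count else NA_integer_,
      completeness_pct = if ("completeness_pct" %in% names(regions))
        regions$completeness_pct else NA_real_,
      quality_tier = if ("quality_tier" %in% names(regions))
        regions$quality_tier else NA_character_,
      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Re-ingest a regions report TSV written by [write_regions()]
#' @param path Path to the TSV.
#' @return Data.frame with internal 0-based half-open coordinates.
#' @export
read_regions_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  conv <- from_1based(tab$start_1based, tab$end_1based)
  tab$start <- conv$start
  tab$end <- conv$end
  tab
}
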