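# Seeded generator of ground-truthed synthetic genomes, prophage implants,
# detector call tables and CRISPR arrays. Every artefact derives its own
# child seed from the single fixture seed, so adding a fixture never
# shifts existing ones; identical seeds give byte-identical fixtures.
# Gene products use the annotation lexicon vocabulary verbatim so the
# rule modules are exercised honestly.

#' Generate a random host genome with sprinkled annotations
#'
#' Bases are i.i.d. at the stated GC content. CDS and tRNA features with
#' host-like products are placed on a regular spacing for integration-site
#' tests.
#'
#' @param length Genome length in bp (>= 50 kb recommended).
#' @param gc GC content in (0, 1).
#' @param seed Integer seed.
#' @param gene_every Mean spacing of sprinkled genes (default 4000).
#' @param genome_id Identifier (default "synth_host").
#' @return A `genome_record`.
#' @export
make_host_genome <- function(length, gc = 0.63, seed = 1L,
                             gene_every = 4000L, genome_id = "synth_host") {
  if (!is.finite(gc) || gc <= 0 || gc >= 1) {
    stop("make_host_genome: gc must lie in (0, 1)")
  }
  withr::with_seed(child_seed(seed, paste0("host_", genome_id)), {
    seq <- random_dna(length, gc)
    products <- c("DNA gyrase subunit A", "methane monooxygenase subunit",
                  "elongation factor Tu", "ribosomal protein S1",
                  "ABC transporter permease", "hypothetical protein",
                  "two-component sensor kinase", "cell division protein FtsZ")
    starts <- seq(500L, length - 2000L, by = gene_every)
    feats <- data.frame(
      feature_id = sprintf("%s_g%03d", genome_id, seq_along(starts)),
      start = starts,
      end = starts + 900L + (seq_along(starts) %% 5L) * 60L,
      strand = rep_len(c("+", "-"), length(starts)),
      kind = "CDS",
      product = sample(products, length(starts), replace = TRUE),
      stringsAsFactors = FALSE)
    # one tRNA and one tmRNA for adjacency tests
    if (length(starts) >= 4) {
      feats$kind[2] <- "tRNA"; feats$product[2] <- "tRNA-Thr"
      feats$end[2] <- feats$start[2] + 76L
      feats$kind[4] <- "tmRNA"; feats$product[4] <- "transfer-messenger RNA, SsrA"
      feats$end[4] <- feats$start[4] + 350L
    }
    genome_record(genome_id, strain = genome_id, sequence = seq,
                  features = feats)
  })
}

PHAGE_BLOCKS <- list(
  integrase = c("integrase"),
  regulation = c("transcriptional regulator", "repressor protein CI"),
  replication = c("DNA polymerase", "replicative DNA helicase"),
  terminase = c("large terminase subunit", "small terminase subunit"),
  structural = c("portal protein", "major capsid protein",
                 "head closure protein", "neck protein",
                 "tail length tape measure protein", "major tail protein"),
  lysis = c("endolysin", "Rz-like spanin"))

#' Build a synthetic prophage cassette
#'
#' Ordered gene blocks (integrase; regulation; replication; terminase;
#' portal/head/neck/tail; lysis) with products drawn verbatim from the
#' annotation lexicon vocabulary. `myovirus = TRUE` swaps the tape measure
#' protein for a tail sheath protein.
#'
#' @param seed Integer seed.
#' @param myovirus Build a contractile-tailed cassette (default FALSE).
#' @param gene_len Mean gene length (default 900).
#' @return List with `sequence`, `features` (cassette-local coordinates,
#'   extra `block` column) and `length`.
#' @export
phage_cassette <- function(seed = 1L, myovirus = FALSE, gene_len = 900L) {
  withr::with_seed(child_seed(seed, "cassette"), {
    blocks <- PHAGE_BLOCKS
    if (myovirus) {
      blocks$structural[5] <- "tail sheath protein"
    }
    feats <- list(); seqs <- character(0); pos <- 0L
    for (b in names(blocks)) {
      for (prod in blocks[[b]]) {
        glen <- gene_len + sample.int(400L, 1L)
        gseq <- random_dna(glen, gc = 0.5)
        spacer <- random_dna(50L, gc = 0.5)
        feats[[length(feats) + 1L]] <- data.frame(
          feature_id = sprintf("phg_%s_%d", b, length(feats) + 1L),
          start = pos, end = pos + glen, strand = "+", kind = "CDS",
          product = prod, block = b, stringsAsFactors = FALSE)
        seqs <- c(seqs, gseq, spacer)
        pos <- pos + glen + 50L
      }
    }
    list(sequence = paste(seqs, collapse = ""),
         features = do.call(rbind, feats), length = pos)
  })
}

#' Delete gene blocks from a cassette
#'
#' Emulates prophage decay: the named blocks are excised from the sequence
#' and the feature table; remaining coordinates are shifted accordingly.
#'
#' @param cassette Output of [phage_cassette()].
#' @param blocks_to_delete Character vector of block names.
#' @return The degraded cassette; `deleted_blocks` records the deletion.
#' @export
degrade_prophage <- function(cassette, blocks_to_delete) {
  if (length(blocks_to_delete) == 0) return(cassette)
  unknown <- setdiff(blocks_to_delete, cassette$features$block)
  if (length(unknown)) stop("degrade_prophage: unknown block(s) ",
                            paste(unknown, collapse = ", "))
  if (all(unique(cassette$features$block) %in% blocks_to_delete)) {
    stop("degrade_prophage: cannot delete every block")
  }
  feats <- cassette$features
  drop <- feats$block %in% blocks_to_delete
  # excise each dropped gene plus its trailing spacer
  cut <- IRanges::reduce(IRanges::IRanges(feats$start[drop] + 1L,
                                          pmin(feats$end[drop] + 50L,
                                               cassette$length)))
  keepseq <- IRanges::setdiff(IRanges::IRanges(1L, cassette$length), cut)
  chars <- strsplit(cassette$sequence, "")[[1]]
  newseq <- paste(chars[unlist(Map(seq, IRanges::start(keepseq),
                                   IRanges::end(keepseq)))], collapse = "")
  shift_of <- function(p) sum(IRanges::width(cut)[IRanges::end(cut) <= p])
  kept <- feats[!drop, , drop = FALSE]
  kept$start <- kept$start - vapply(kept$start, shift_of, numeric(1))
  kept$end <- kept$end - vapply(kept$end, shift_of, numeric(1))
  list(sequence = newseq, features = kept, length = nchar(newseq),
       deleted_blocks = blocks_to_delete)
}

#' Implant a prophage cassette into a host genome
#'
#' Inserts `att + cassette + att` at `position` (intergenic by default;
#' `disrupt_gene = TRUE` drops the implant mid-CDS instead). Host features
#' downstream of the insertion are shifted; cassette features are added in
#' host coordinates. The returned truth records the implant interval
#' (including both att copies), the att repeat and the cassette genes.
#'
#' @param host A `genome_record`.
#' @param cassette Output of [phage_cassette()] (possibly degraded).
#' @param position Insertion point (internal coordinate); `NULL` picks an
#'   intergenic (or, with `disrupt_gene`, mid-gene) site at random.
#' @param att_len Direct repeat length (default 15).
#' @param seed Integer seed.
#' @param phage_id Identifier recorded in the truth.
#' @param disrupt_gene Insert mid-CDS (default FALSE).
#' @return List with `genome` (new `genome_record`) and `truth` (list:
#'   `phage_id, start, end, att_seq, att_len, degraded, deleted_blocks,
#'   disrupted_gene`).
#' @export
implant_prophage <- function(host, cassette, position = NULL, att_len = 15L,
                             seed = 1L, phage_id = "phi1",
                             disrupt_gene = FALSE) {
  withr::with_seed(child_seed(seed, paste0("implant_", phage_id)), {
    feats <- host$features
    if (is.null(position)) {
      if (disrupt_gene) {
        # disrupt an informatively annotated CDS: hypothetical proteins are
        # excluded from the flank homologue comparison and so carry no
        # disruption evidence
        cds <- feats[feats$kind == "CDS" & nzchar(feats$product) &
                       tolower(feats$product) != "hypothetical protein", ,
                     drop = FALSE]
        g <- cds[sample.int(nrow(cds), 1L), ]
        position <- as.integer((g$start + g$end) %/% 2L)
      } else {
        gaps <- IRanges::setdiff(
          IRanges::IRanges(2000L, host$length - 2000L),
          IRanges::IRanges(feats$start + 1L, feats$end))
        gaps <- gaps[IRanges::width(gaps) > 200L]
        gi <- sample.int(length(gaps), 1L)
        position <- IRanges::start(gaps)[gi] + IRanges::width(gaps)[gi] %/% 2L
      }
    }
    disrupted <- feats$feature_id[feats$start < position & feats$end > position]
    if (!disrupt_gene && length(disrupted) > 0) {
      stop("implant_prophage: position ", position, " falls inside gene ",
           disrupted[1], "; set disrupt_gene = TRUE to allow")
    }
    # avoid micro-homology at the junctions (insert edge repeating the next
    # or previous host base), so the implanted boundaries are the unique
    # synteny breakpoints
    h_next <- substr(host$sequence, position + 1L, position + 1L)
    h_prev <- substr(host$sequence, position, position)
    repeat {
      att <- random_dna(att_len, gc = 0.45)
      if (substr(att, 1L, 1L) != h_next &&
          substr(att, att_len, att_len) != h_prev) break
    }
    # two-base pads between each att copy and the cassette, chosen to
    # mismatch the flank context of the other copy, so the direct repeat
    # cannot extend past the planted att even with one tolerated mismatch
    bases <- c("A", "C", "G", "T")
    not_base <- function(b) {
      pool <- if (b %in% bases) setdiff(bases, b) else bases
      pool[sample.int(length(pool), 1L)]
    }
    pad1 <- paste0(not_base(substr(host$sequence, position + 1L, position + 1L)),
                   not_base(substr(host$sequence, position + 2L, position + 2L)))
    pad2 <- paste0(not_base(substr(host$sequence, position - 1L, position - 1L)),
                   not_base(substr(host$sequence, position, position)))
    insert <- paste0(att, pad1, cassette$sequence, pad2, att)
    ins_len <- nchar(insert)
    newseq <- paste0(substr(host$sequence, 1, position),
                     insert,
                     substr(host$sequence, position + 1L, host$length))
    shifted <- feats
    move <- shifted$start >= position
    shifted$start[move] <- shifted$start[move] + ins_len
    shifted$end[shifted$end > position] <-
      shifted$end[shifted$end > position] + ins_len
    ph <- cassette$features
    ph$start <- ph$start + position + att_len + 2L
    ph$end <- ph$end + position + att_len + 2L
    ph$feature_id <- paste0(phage_id, "_", ph$feature_id)
    ph$block <- NULL
    allf <- rbind(shifted, ph)
    allf <- allf[order(allf$start), , drop = FALSE]
    rownames(allf) <- NULL
    genome <- genome_record(host$genome_id, host$strain, newseq, allf)
    truth <- list(phage_id = phage_id, start = position,
                  end = position + ins_len, att_seq = att, att_len = att_len,
                  degraded = !is.null(cassette$deleted_blocks),
                  deleted_blocks = cassette$deleted_blocks,
                  disrupted_gene = if (length(disrupted)) disrupted[1] else NA_character_)
    list(genome = genome, truth = truth)
  })
}

#' Simulate noisy multi-detector candidate calls
#'
#' Per detector, each implant is reported with probability `1 - miss_rate`
#' with Gaussian boundary jitter; false positives are placed uniformly in
#' non-implant territory at `fp_rate` per 100 kb. PHASTEST/VIBRANT raw
#' scores are drawn with true calls stochastically higher; Phigaro/PhiSpy
#' calls carry no score (as in their native outputs).
#'
#' @param truths List of implant truth records (each with `start`, `end`).
#' @param genome_id,genome_length Genome the calls refer to.
#' @param detectors Detector names (subset of phastest/phigaro/vibrant/phispy).
#' @param miss_rate,fp_rate Rates in `[0, 1)`.
#' @param boundary_jitter_sd Jitter SD in bp (default 0).
#' @param seed Integer seed.
#' @return Candidate data.frame in the normalized layout of
#'   [ingest_detector_table()].
#' @export
simulate_detector_calls <- function(truths, genome_id, genome_length,
                                    detectors = c("phastest", "phigaro",
                                                  "vibrant", "phispy"),
                                    miss_rate = 0, fp_rate = 0,
                                    boundary_jitter_sd = 0, seed = 1L) {
  if (miss_rate < 0 || miss_rate >= 1 || fp_rate < 0 || fp_rate >= 1) {
    stop("simulate_detector_calls: rates must lie in [0, 1)")
  }
  withr::with_seed(child_seed(seed, paste0("calls_", genome_id)), {
    rows <- list()
    scored <- c(phastest = TRUE, phigaro = FALSE, vibrant = TRUE,
                phispy = FALSE)
    for (det in detectors) {
      for (tr in truths) {
        if (stats::runif(1) < miss_rate) next
        j <- if (boundary_jitter_sd > 0)
          round(stats::rnorm(2, 0, boundary_jitter_sd)) else c(0L, 0L)
        s <- max(0L, min(tr$start + j[1], tr$end - 1000L))
        e <- min(genome_length, max(tr$end + j[2], s + 1000L))
        pg <- 10L + stats::rpois(1, 6)
        # true calls carry the detector's nominal full score so that a
        # noiseless fixture always passes the score-vs-run-mean criterion
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = genome_id, start = as.integer(s), end = as.integer(e),
          detector = det,
          raw_score = if (scored[[det]])
            c(phastest = 120, vibrant = 90)[[det]] else NA_real_,
          phage_gene_count = pg, total_gene_count = pg + stats::rpois(1, 15),
          att_flag = NA, stringsAsFactors = FALSE)
      }
      n_fp <- stats::rpois(1, fp_rate * genome_length / 1e5)
      for (f in seq_len(n_fp)) {
        len <- 5000L + sample.int(10000L, 1L)
        s <- sample.int(max(1L, genome_length - len), 1L)
        pg <- stats::rpois(1, 4)
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = genome_id, start = s, end = s + len, detector = det,
          raw_score = if (scored[[det]]) round(stats::rnorm(1, 50, 10), 1)
          else NA_real_,
          phage_gene_count = pg, total_gene_count = pg + stats::rpois(1, 15),
          att_flag = NA, stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) return(empty_candidates())
    cand <- do.call(rbind, rows)
    cand$score_class <- ifelse(is.na(cand$raw_score), "missing", "unclassified")
    cand[c("genome_id", "start", "end", "detector", "raw_score", "score_class",
           "phage_gene_count", "total_gene_count", "att_flag")]
  })
}

#' Build a CRISPR fixture with known protospacer origins
#'
#' Spacers are sampled from the phage sequences (protospacers) and mutated
#' at `mutation_rate` substitutions per base; random spacers with no phage
#' origin are interleaved. Optionally an ancestral shared block is copied
#' into several arrays at their distal ends.
#'
#' @param phages Named list of phage DNA strings.
#' @param n_spacers Spacers per array (>= 1).
#' @param mutation_rate Per-base substitution probability.
#' @param n_arrays Number of arrays (default 1).
#' @param frac_protospacer Fraction of spacers drawn from phages (default 0.5).
#' @param shared_block_len Length of an ancestral block copied across all
#'   arrays at the distal end (0 = none).
#' @param spacer_len Spacer length (default 30).
#' @param seed Integer seed.
#' @return List with `arrays` (list of `crispr_array`), `spacer_table`
#'   (data.frame `spacer_id, seq, genome_id, array_id, index_from_leader`)
#'   and `truth` (data.frame `spacer_id, phage_id, pos, n_mutations`; one
#'   row per protospacer-derived spacer).
#' @export
make_crispr_fixture <- function(phages, n_spacers = 20L, mutation_rate = 0,
                                n_arrays = 1L, frac_protospacer = 0.5,
                                shared_block_len = 0L, spacer_len = 30L,
                                seed = 1L) {
  if (n_spacers < 1) stop("make_crispr_fixture: n_spacers must be >= 1")
  if (length(phages) == 0) stop("make_crispr_fixture: phages must be non-empty")
  withr::with_seed(child_seed(seed, "crispr_fixture"), {
    shared <- if (shared_block_len > 0)
      replicate(shared_block_len, random_dna(spacer_len, 0.5)) else character(0)
    arrays <- list(); tabs <- list(); truths <- list()
    for (a in seq_len(n_arrays)) {
      aid <- sprintf("synthArray%d", a)
      gid <- sprintf("synth_strain%d", a)
      n_own <- n_spacers - length(shared)
      spacers <- character(n_own)
      for (i in seq_len(n_own)) {
        if (stats::runif(1) < frac_protospacer) {
          pi <- sample.int(length(phages), 1L)
          pseq <- phages[[pi]]
          pos <- sample.int(nchar(pseq) - spacer_len, 1L)
          sp <- substr(pseq, pos, pos + spacer_len - 1L)
          nmut <- stats::rbinom(1, spacer_len, mutation_rate)
          if (nmut > 0) {
            idx <- sample.int(spacer_len, nmut)
            ch <- strsplit(sp, "")[[1]]
            for (m in idx) {
              ch[m] <- sample(setdiff(c("A", "C", "G", "T"), ch[m]), 1L)
            }
            sp <- paste(ch, collapse = "")
          }
          if (stats::runif(1) < 0.5) sp <- revcomp(sp)
          spacers[i] <- sp
          truths[[length(truths) + 1L]] <- data.frame(
            spacer_id = sprintf("%s_s%d", aid, i - 1L),
            phage_id = names(phages)[pi], pos = pos - 1L,
            n_mutations = nmut, stringsAsFactors = FALSE)
        } else {
          spacers[i] <- random_dna(spacer_len, 0.5)
        }
      }
      spacers <- c(spacers, shared)  # ancestral block at the distal end
      arr <- crispr_array(aid, gid, spacers, cas_type = "I-E",
                          repeat_consensus = random_dna(32L, 0.4))
      arrays[[a]] <- arr
      tabs[[a]] <- data.frame(
        spacer_id = sprintf("%s_s%d", aid, seq_along(spacers) - 1L),
        seq = spacers, genome_id = gid, array_id = aid,
        index_from_leader = seq_along(spacers) - 1L, stringsAsFactors = FALSE)
    }
    list(arrays = arrays, spacer_table = do.call(rbind, tabs),
         truth = if (length(truths)) do.call(rbind, truths) else
           data.frame(spacer_id = character(0), phage_id = character(0),
                      pos = integer(0), n_mutations = integer(0),
                      stringsAsFactors = FALSE))
  })
}
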