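#' Pipeline configuration
#'
#' Builds the configuration object shared by every stage of the prophage
#' surveillance pipeline. Every numeric knob used anywhere in the package
#' lives here, with the defaults the pipeline was designed around: a
#' consensus call must be supported by at least two detectors, exceed 10 kb
#' and carry at least ten phage-specific genes; candidate calls closer than
#' 3 kb are merged; boundary refinement looks 20 kb beyond each called
#' boundary; flanking-gene analysis uses a 1000-nt window; ICTV demarcation
#' thresholds are 95% (species) and 70% (genus); spacer re-alignment uses
#' match reward 1, mismatch penalty 1, gap open 10 and gap extension 2, with
#' at most 2 mismatches tolerated and target-decoy FDR controlled at 0.05.
#'
#' @param min_detectors Minimum number of supporting detectors (criterion of
#'   multi-tool evidence). Default 2.
#' @param min_length_bp Minimum consensus region length in bp (strictly
#'   exceeded). Default 10000.
#' @param min_phage_genes Minimum number of phage-specific genes. Default 10.
#' @param merge_gap_bp Candidates separated by at most this many bp are
#'   merged. Default 3000.
#' @param extension_bp Window added on both sides of a region before synteny
#'   refinement. Default 20000.
#' @param flank_window_bp Window around a refined boundary searched for
#'   neighbouring genes. Default 1000.
#' @param species_threshold_pct,genus_threshold_pct ICTV intergenomic
#'   similarity demarcation thresholds (percent). Defaults 95 and 70.
#' @param match_reward,mismatch_penalty,gap_open,gap_extend Nucleotide
#'   re-alignment costs for spacer-protospacer scoring. Defaults 1, 1, 10, 2.
#' @param max_mismatches Maximum mismatches (edit operations) tolerated in a
#'   spacer match. Default 2.
#' @param fdr_alpha Target-decoy FDR threshold. Default 0.05.
#' @param anchor_k Synteny anchor k-mer length. Default 21.
#' @param att_min_len Minimum attL/attR direct repeat length. Default 11.
#' @param att_max_mismatch Maximum mismatches between the two att repeats.
#'   Default 1.
#' @param att_search_bp Width of the window centred on each boundary searched
#'   for att repeats. Default 2000.
#' @param chain_gap_bp Maximum gap between consecutive anchors in one synteny
#'   chain, on either sequence. Default 5000.
#' @param strict_all If TRUE all five selection criteria (including att
#'   presence and the score criterion even without a scoring detector) are
#'   mandatory. Default FALSE.
#' @param rng_seed Integer seed driving every stochastic step. Default 1.
#'
#' @return A list of class `pw_config`.
#' @export
#' @examples
#' cfg <- pw_config()
#' cfg$min_length_bp
pw_config <- function(min_detectors = 2L,
                      min_length_bp = 10000L,
                      min_phage_genes = 10L,
                      merge_gap_bp = 3000L,
                      extension_bp = 20000L,
                      flank_window_bp = 1000L,
                      species_threshold_pct = 95,
                      genus_threshold_pct = 70,
                      match_reward = 1L,
                      mismatch_penalty = 1L,
                      gap_open = 10L,
                      gap_extend = 2L,
                      max_mismatches = 2L,
                      fdr_alpha = 0.05,
                      anchor_k = 21L,
                      att_min_len = 11L,
                      att_max_mismatch = 1L,
                      att_search_bp = 2000L,
                      chain_gap_bp = 5000L,
                      strict_all = FALSE,
                      rng_seed = 1L) {
  cfg <- list(
    min_detectors = as.integer(min_detectors),
    min_length_bp = as.integer(min_length_bp),
    min_phage_genes = as.integer(min_phage_genes),
    merge_gap_bp = as.integer(merge_gap_bp),
    extension_bp = as.integer(extension_bp),
    flank_window_bp = as.integer(flank_window_bp),
    species_threshold_pct = species_threshold_pct,
    genus_threshold_pct = genus_threshold_pct,
    match_reward = as.integer(match_reward),
    mismatch_penalty = as.integer(mismatch_penalty),
    gap_open = as.integer(gap_open),
    gap_extend = as.integer(gap_extend),
    max_mismatches = as.integer(max_mismatches),
    fdr_alpha = fdr_alpha,
    anchor_k = as.integer(anchor_k),
    att_min_len = as.integer(att_min_len),
    att_max_mismatch = as.integer(att_max_mismatch),
    att_search_bp = as.integer(att_search_bp),
    chain_gap_bp = as.integer(chain_gap_bp),
    strict_all = isTRUE(strict_all),
    rng_seed = as.integer(rng_seed)
  )
  num <- c("min_detectors", "min_length_bp", "min_phage_genes",
           "merge_gap_bp", "extension_bp", "flank_window_bp",
           "species_threshold_pct", "genus_threshold_pct",
           "match_reward", "mismatch_penalty", "gap_open", "gap_extend",
           "max_mismatches", "anchor_k", "att_min_len",
           "att_search_bp", "chain_gap_bp")
  for (f in num) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("pw_config: '", f, "' must be strictly positive")
    }
  }
  if (cfg$att_max_mismatch < 0) stop("pw_config: att_max_mismatch must be >= 0")
  if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1) {
    stop("pw_config: fdr_alpha must lie in (0, 1)")
  }
  if (cfg$species_threshold_pct <= cfg$genus_threshold_pct) {
    stop("pw_config: species threshold must exceed genus threshold")
  }
  class(cfg) <- "pw_config"
  cfg
}

#' @export
print.pw_config <- function(x, ...) {
  cat("<pw_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Derive a reproducible child seed from a parent seed and a label, so adding
# a fixture never shifts the streams of existing ones. Kept below 2^31.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
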