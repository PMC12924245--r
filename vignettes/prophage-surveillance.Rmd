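---
title: "Prophage surveillance: methods and design notes"
author: "phagewatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prophage surveillance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagewatch)
```

# The problem

Temperate phages integrate into bacterial chromosomes and persist as
prophages. In open, non-sterile industrial cultivation — methane-fed
*Methylococcus* consortia are the motivating case — a stress-triggered
switch of an intact prophage to the lytic cycle can lyse the producer
culture. Surveillance therefore needs four answers per genome: where are
the prophages, are their boundaries trustworthy, could they still be
induced, and does the host's CRISPR record show prior encounters with
them.

No single detector answers the first question reliably; the tools differ
in models and training data and their calls overlap only partially.
phagewatch therefore treats detectors as noisy voters and implements the
downstream consensus, refinement, classification and immunity analysis.

# Consensus model

Candidates are intervals with a detector label, an optional raw score and
gene counts. Internally all coordinates are 0-based half-open; every
human-facing table is 1-based inclusive, and region lengths print as
`(end − start) / 1000` rounded half-up to one decimal. Merging closes
gaps of at most `merge_gap_bp` (default 3000 bp — "closely situated" is a
judgement call; the default is small against typical prophage spacing and
is configurable).

The five selection criteria are applied per merged region. Three are
mandatory: multi-detector support (`min_detectors` = 2), length strictly
above `min_length_bp` (10 000 bp), and at least `min_phage_genes` (10)
phage-specific genes. The score criterion compares a member's
PHASTEST/VIBRANT raw score with that detector's mean over **all**
candidates of the run — per detector, because the two score scales are
not commensurable — and is enforced only when such a member exists.
att-site presence is recorded as evidence rather than required, because
att detection quality depends on boundary quality, which is refined only
later; a `strict_all` switch makes criteria 4 and 5 mandatory for users
who want the conservative reading. CheckV is ingested, never run; the
quality gate retains Medium, High and Complete tiers and is skipped (with
a warning) when no CheckV table is supplied.

# Boundary refinement and att sites

The region, extended by `extension_bp` (20 kb) on both sides, is compared
with a prophage-free reference strain. Instead of a full progressive
aligner the package uses anchors: k-mers (`anchor_k` = 21) occurring
exactly once in each sequence counting both strands, chained per strand by
a longest-increasing-subsequence dynamic programme with gaps capped at
`chain_gap_bp` (5 kb) on either sequence. Adjacent exact runs may overlap
by up to k − 1 bp around an indel, and the chain extractor is greedy by
score with query overlaps forbidden. The insertion is the query interval
covered by no block and overlapping the called region most; the refined
boundaries are the adjacent block edges, clamped to the extension window.
When a side has no flanking block the original boundary is kept with a
warning. Precomputed XMFA blocks can substitute for the built-in aligner
when a whole-genome alignment is preferred.

att detection searches `att_search_bp` (2 kb) windows centred on the two
boundaries for the best pair of direct repeats with length ≥ `att_min_len`
(11 bp) and at most `att_max_mismatch` (1) mismatches. Published att sites
are typically ~10–100 bp, hence the defaults; all three are configurable.
Candidate pairs are seeded by shared exact words of length
`att_min_len %/% (att_max_mismatch + 1)` (so a qualifying repeat always
contains a seed) and extended outward under the mismatch budget, never
starting or ending on a mismatch. Pairs are ranked by **fewer mismatches
first**, then longer repeat, then smaller left start: the recombination
core of a genuine att pair is exact, and preferring a marginally longer
imperfect repeat over a perfect one would let chance background repeats
shadow real att sites. N matches nothing, including another N.

# Annotation, morphology, inducibility

The reference analysis maps genes to a protein-family database; the
decision layer that matters downstream is re-expressed here as an
editable keyword lexicon over product strings
(`inst/extdata/functional_lexicon.tsv`, priority = file order, most
specific keyword first, e.g. "tail sheath" before "tail"). The mapping is
total: empty products and "hypothetical protein" map to `hypothetical`,
anything unmatched to `other`. Morphology follows the structural-protein
rule — tail sheath ⇒ myovirus; tape measure without sheath ⇒ siphovirus;
otherwise undetermined. Inducibility demands five blocks: (i) integrase
or transposase, (ii) portal + head + a tail component (neck optional),
(iii) a terminase subunit, (iv) a lysis gene (endolysin/spanin/holin),
(v) a nucleic-acid-metabolism gene. Integrase *position* (typically at
the prophage edge) is reported but not enforced: transposable-phage
cassettes legitimately carry a transposase elsewhere.

# Intergenomic similarity and clustering

For a pair of prophage sequences the seed-and-extend aligner chains
shared unique k-mer anchors (both strands), closes inter-run gaps of up
to 2 kb on both sequences by global pairwise alignment
(`Biostrings::pairwiseAlignment`), merges the aligned segments per genome
(each locus used once, best chain first) and counts identical positions.
The similarity is `100 · (id_a + id_b) / (len_a + len_b)`, the standard
two-way intergenomic similarity used for phage taxonomy. Identity of a
sequence with itself is 100 by construction when its k-mers are unique;
heavily repetitive sequences are covered through the gap-alignment path.
On sequences ≤ 2 kb the identity counts agree with a full local dynamic
programming oracle within 2 % (tested). Clustering is single linkage on
`100 − similarity`, cut at the species (95 %) and genus (70 %)
demarcation thresholds; cutting is inclusive (a pair at exactly the
threshold shares a cluster), and the species partition provably refines
the genus partition. Single linkage at a fixed threshold is a
deliberately simple reading of threshold-based demarcation; distance
methods with optimized clustering can place borderline pairs (similarity
far below the genus cut) differently, so cluster memberships near the
threshold should be read with that in mind.

# CRISPR immunity

Arrays are stored leader-first (index 0 = most recently acquired);
flipping an array reverse-complements the spacers and reverses their
order, an involution. Spacer identity is evaluated modulo reverse
complement everywhere. Shared blocks are maximal runs of consecutive
shared spacers between two arrays, reported in both co-linear and
reversed orientation; a shared ancestral block is expected at the distal
end, so a block touching the predicted leader end flips the array
(orientation `block_corrected`), while blocks at both ends leave the
orientation `unknown` with a warning.

Matching scans both strands of every prophage for spacer hits within 2
edit operations (`Biostrings::matchPattern` with indels), then re-aligns
each hit window under the stated costs — match +1, mismatch −1, gap open
10, gap extension 2, a gap of length L costing `10 + 2 L` (the open cost
does not include the first extension; the paper-stated costs leave the
convention open and this one is recorded). Hits with more than
`max_mismatches` (2) substitutions are discarded; the score identity
`score = matches − mismatches − Σ(gap costs)` is re-verified in tests for
every emitted hit. An exact hit of a spacer on a prophage of its own
genome is flagged as a potential self-target.

FDR control is empirical target-decoy: each spacer is dinucleotide-
shuffled (Altschul–Erickson Eulerian-path shuffle, exactly preserving
dinucleotide composition, seeded) `n_decoy_sets` times (default 10; 20
spacers hence 200 decoys). For a score threshold s the FDR estimate is
the per-set-averaged decoy hit count at ≥ s divided by the real hit count
at ≥ s, clamped to 1; q-values are the running minima over admissible
thresholds, and hits with q ≤ `fdr_alpha` (0.05) are retained. This is a
per-hit FDR: the reference tool aggregates multiple spacers per
phage-genome pair into a combined score before thresholding, so match
*counts* are structurally comparable but not identical, and deviations on
real data should be reported rather than absorbed.

# Integration sites

Genes intersecting a 1000-nt window around each refined boundary are the
flank set; the prophage's own genes (fully inside the region) are not,
but a host gene straddling a boundary is, as direct disruption evidence.
Hypothetical proteins are listed yet excluded from comparison. A
homologue is a feature with the same product string in the syntenic
reference locus — annotation-based matching, since the reference analysis
compared annotations and lengths; among multi-copy products the
nearest-length copy is used. Length preservation is strict equality by
default (`tolerance_bp = 0`, exposed for jittery annotations). A missing
homologue or a length change classifies the insertion gene-disrupting; an
uncomparable side with a clean other side gives `indeterminate`
(conservative); otherwise intergenic. Duplicate copies of flank products
are counted genome-wide by exact product match, and tRNA/tmRNA adjacency
within the window is reported.

# The synthetic-fixture generator

The generator emulates the study design at desk scale: host genomes are
i.i.d. bases at a set GC (default 0.63, a typical methanotroph genome
composition) with sprinkled CDS/tRNA/tmRNA annotations; prophage
cassettes carry the essential blocks in canonical order (integrase →
regulation → replication → terminase → portal/head/neck/tail → lysis)
with products drawn verbatim from the lexicon; implants insert
`att + cassette + att` at intergenic (or deliberately mid-CDS) positions;
block deletion emulates decayed prophages; detector simulation reports
implants with configurable miss rate, Gaussian boundary jitter and
uniform false positives; CRISPR fixtures sample protospacers with per-base
mutation and interleave random spacers, recording exact origins.

Three constructions keep the ground truth exact rather than approximate:
implant junctions avoid micro-homology with the host (so the synteny
breakpoints are unique and noiseless refinement is exact, not ±1);
two-base junction pads prevent the att repeat from extending into
chance-matching context; and noiseless detector calls carry a detector's
nominal full score so the score-vs-run-mean criterion cannot eliminate a
true region in a run without false positives. `disrupt_gene` targets an
informatively annotated CDS, because disrupting a hypothetical protein
leaves no admissible evidence under the flank-comparison rule — a true
limitation of annotation-based integrity checks that the generator makes
visible rather than hides.

What the generator does **not** emulate: real base composition structure
(coding bias, GC skew), homology between prophages and host, repeat
families, mosaic phage evolution, or detector-specific error profiles.
Passing the synthetic suite therefore demonstrates algorithmic
correctness on well-posed inputs, not detector-level accuracy on real
genomes.

All randomness flows from one integer seed through a label-hashed child
seed per artefact, so adding a fixture never shifts existing ones and
identical seeds give byte-identical fixtures.

# Packaged benchmark tables

`inst/extdata/benchmark_regions.tsv` and `benchmark_checkv.tsv`
transcribe the published per-prophage report (coordinates, protein
counts, completeness, quality) of the nine-genome *Methylococcus* study
the pipeline is modelled on. Two files are **synthetic stand-ins**,
flagged by filename: `synthetic_detector_calls_s2.tsv` reconstructs a
per-tool candidate table from the published per-tool totals (21 + 19 +
14 + 14 = 68), placing true calls at the published region coordinates and
single-detector, below-threshold false calls elsewhere, so the consensus
stage can be exercised end-to-end; `synthetic_benchmark_gene_products.tsv`
transcribes the prose descriptions of each prophage's gene content
(including the deletions in KN2-R2 and McNor-R1) into product strings.
They are inputs for testing the decision layers, not copies of the
original supplementary data.

# Test problem sizes

The suite exercises: interval merging against a brute-force position-set
oracle on 1000 random instances; 100 seeded implants (50-kb hosts,
~15-kb cassettes) for noiseless-exact and jittered (SD 2000 bp) boundary
recovery; 10 att plant-and-recover seeds; similarity against the DP
oracle on 1.8–2-kb pairs; 20 mutated protospacers against two 20-kb
phages with 200 decoys for sensitivity and FDR; and 100 seeded
integration trials. `scripts/acceptance.R` re-runs the same computations
at 30 implants and writes the resulting quantities as JSON.

# Known limitations

* Detector-native parsers are best-effort adapters; the normalized TSV is
  the stable contract.
* The anchor aligner assumes unique flanking sequence; boundaries inside
  long repeats fall back to the called coordinates with a warning.
* Homologue identification is annotation-string based; diverged or
  re-annotated references need sequence-level comparison, which is out of
  scope.
* Per-hit FDR differs structurally from multi-spacer aggregated scoring.
* Completeness is ingested from CheckV, never recomputed.
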