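# phagewatch

Prophage surveillance for bacterial genome sets, built for the situation a
methanotroph (*Methylococcus*) production facility faces: cultivation is
open and non-sterile, temperate phages integrate into production strains,
and a stress-induced switch to the lytic cycle can collapse a bioreactor.
The package turns the outputs of standard prophage detectors into a
curated, annotated, immunity-aware prophage inventory — without running any
external tool itself.

## What it does

Given per-genome candidate tables from prophage detectors (PHASTEST,
Phigaro, VIBRANT, PhiSpy, or any tool mapped onto a normalized TSV), the
pipeline:

1. **Consensus calling** — merges overlapping or closely situated calls
   (gap ≤ 3 kb) and applies five selection criteria: (1) support by ≥ 2
   detectors, (2) length > 10 kb, (3) ≥ 10 phage-specific genes, (4) a
   PHASTEST/VIBRANT raw score at or above that detector's run-wide mean
   (when such a member exists), (5) presence of att sites (recorded as
   evidence). Regions are then gated on ingested CheckV quality tiers
   (Medium/High/Complete retained).
2. **Boundary refinement** — aligns each region ± 20 kb against a
   prophage-free reference strain with a k-mer anchor-and-chain aligner
   (k = 21, chain gap ≤ 5 kb); the insertion is the query interval no
   synteny block covers, and the boundaries snap to the flanking block
   edges. Precomputed whole-genome-aligner blocks can be ingested from
   XMFA instead.
3. **att detection** — the best pair of direct repeats (≥ 11 bp, ≤ 1
   mismatch) in 2-kb windows centred on the two boundaries.
4. **Annotation rules** — a keyword lexicon maps gene products to
   functional categories; a tail sheath protein ⇒ myovirus, a tape measure
   protein without a sheath ⇒ siphovirus; a prophage is judged *intact*
   (potentially inducible) iff all five essential gene blocks are present:
   integrase/transposase, structural set (portal + head + tail), a
   terminase subunit, a lysis gene, and a nucleic-acid-metabolism gene.
5. **Intergenomic similarity** — a seed-and-extend aligner computes, per
   pair of prophages, `100 · (id_a + id_b) / (len_a + len_b)` over merged
   aligned segments; single-linkage clustering at the ICTV demarcation
   thresholds (species 95 %, genus 70 %).
6. **CRISPR immunity** — leader-polarized spacer arrays (ingested from
   CRISPRCasFinder JSON / TSV or detected in synthetic data), shared
   spacer blocks across strains (identity modulo reverse complement),
   block-based orientation correction, acquisition-recency ranks, and
   spacer→prophage matching (≤ 2 mismatches; match +1, mismatch −1, gap
   open 10, extension 2) with empirical target-decoy FDR control at
   q ≤ 0.05 against dinucleotide-shuffled decoys.
7. **Integration sites** — genes within 1000 nt of each refined boundary
   are compared with their product-string homologues in the reference
   strain (presence and exact length); verdicts are intergenic /
   gene-disrupting / indeterminate, with duplicate-copy counts and
   tRNA/tmRNA adjacency.

A seeded synthetic-fixture generator (host genomes, prophage cassettes
with att repeats, optional block deletions, noisy multi-detector calls,
CRISPR arrays with known protospacer origins) makes every stage testable
offline with exact ground truth.

## Worked example

The package ships a desk-scale benchmark: a candidate table with 68
detector calls over nine genomes and the matching CheckV tiers.

```r
library(phagewatch)
cand  <- ingest_detector_table(system.file("extdata",
           "synthetic_detector_calls_s2.tsv", package = "phagewatch"))
checkv <- ingest_checkv(system.file("extdata",
           "benchmark_checkv.tsv", package = "phagewatch"))
res <- call_consensus(cand, checkv)
nrow(res$final)
#> [1] 11
head(res$final[, c("region_id", "genome_id")], 3)
#>   region_id genome_id
#> 1   16-5-R1      16-5
#> 2   16-5-R2      16-5
#> 3   16-5-R3      16-5
sort(length_kb(res$final$start, res$final$end))
#>  [1] 29.1 36.0 41.2 45.6 45.9 45.9 47.3 52.5 56.7 67.7 71.4
```

Of the 68 candidates, the five criteria and the quality gate retain 11
prophage regions in 5 of the 9 strains (55.6 %); region lengths range from
29.1 to 71.4 kb. Annotating the packaged per-prophage gene tables
classifies 9 of the 11 as intact (potentially inducible) and two —
KN2-R2 and McNor-R1 — as defective.

The same flow is available from the shell:

```sh
Rscript inst/scripts/phagewatch.R run-all \
    --candidates calls.tsv --checkv checkv.tsv --out results/
```

## Layout

- `R/` — implementation (IO, consensus, synteny/att, annotation,
  similarity, CRISPR, integration sites, synthetic fixtures, pipeline).
- `inst/extdata/` — lexicon and plain-text benchmark tables
  (`synthetic_*` files are constructed stand-ins, see the vignette).
- `vignettes/prophage-surveillance.Rmd` — the methods vignette: models,
  parameters, numerical choices, limitations.
- `tests/testthat/` — unit, property and acceptance tests.
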