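---
title: "Genome size estimation: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome size estimation: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomesizer)
```

## Why these estimators

Genome assemblies routinely under-represent repetitive DNA: when repeat
copies are more similar than the sequencing error rate can distinguish, an
assembler merges them into one consensus, so assembly size is a lower
bound on genome size. This package implements the two standard read-based
correctives — the k-mer spectrum estimator and modal-coverage
(Lander–Waterman) extrapolation — together with the cytometric converters
that turn flow-cytometry (FCM) and Feulgen-densitometry (FIAD)
measurements into genome sizes, and a simulator that generates repeat-rich
genomes with known truth so that each estimator's behaviour under repeat
collapse can be demonstrated rather than assumed.

## The models

**k-mer estimator.** Every length-k window over A/C/G/T in the reads is
counted in canonical form (the lexicographic minimum of the word and its
reverse complement; k is restricted to odd values so no word is its own
reverse complement). If single-copy sequence is sequenced to depth C with
reads of length L, each genomic k-mer is seen about `C_k = C (L − k + 1)/L`
times, so the spectrum shows a genomic peak at multiplicity ~C_k, and

    G = (number of k-mers at or above the error cutoff) / C_k.

Sequencing errors create a spike of near-unique k-mers at multiplicity 1;
the `"auto"` cutoff walks up the histogram to the first strict local
minimum (the valley between error spike and genomic peak) and fails with a
diagnostic when counts are monotone decreasing, which is what low-coverage
data look like. Whether k-mers *below* the cutoff enter the numerator is a
convention; both are implemented and excluding them is the default, as is
standard practice. Ties at the peak break toward the smaller multiplicity
so output is deterministic.

**Depth estimator.** With per-base mapped depth d_i and modal depth M
(zero-depth positions are excluded from the modal search — they would
dominate sparse profiles — but contribute 0 to the sum),

    G = sum(d_i) / M.

The repeat-collapse correction is automatic: a repeat whose N copies are
collapsed to one consensus receives N-fold depth there, so its assembly
positions are counted N times. On an exactly uniform profile this reduces
to `G = N·L / C`, the Lander–Waterman form, which is also exposed
directly.

**Cytometric converters.** FCM: `pg = FL_sample × pg_standard /
FL_standard` against co-stained internal standards (built-ins: chicken
2.50 pg, human 7.00 pg, trout 5.2 pg, fruit fly 0.40 pg). FIAD: `pg_c =
(pg_s / IOD_s) × IOD_c`, with an OLS calibration line of pg on IOD across
standards as the staining-linearity check. Conversions use `1 pg = 0.978
Gb`; 1C is half the somatic 2C (valid only absent chromatin diminution,
which is why the gamete-doubling check `derive_2C_from_gamete()` exists).
When a specimen is measured against two standards the pg values are
averaged *before* converting to Gb.

**Congruence.** Assemblies are compared without assuming synteny: shred
each into non-overlapping 240 bp synthetic reads, align to the other
assembly with a seed-and-extend local aligner (exact 11-mer seeds, both
strands, windowed affine Smith–Waterman with full traceback) under
blastn-style scoring (+1 match, −1 mismatch, gap of length l costs
3 + 2l), and report the mean per-read query cover (union of reported
alignment intervals) and the fraction of mapped reads whose best alignment
exceeds 95% identity (strict inequality).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `k` | 21–31 odd | bases | classic sweep; odd avoids palindromic k-mers |
| `error_cutoff` | `"auto"` | multiplicity | first strict local minimum |
| `min_depth` | 1 | depth | depth-0 always excluded from the mode |
| `fragment_length` | 240 | bases | shredding unit for congruence |
| `word` | 11 | bases | classic blastn seed length |
| `evalue` | 1e-10 | — | converted to a raw-score floor (below) |
| `max_alignments` | 10 | — | alignments reported per read |
| `retained_copies_per_family` | 1 | copies | collapse severity |

Significance uses the ungapped Karlin–Altschul relation
`E = K m n e^{−λS}` with λ solved from the base composition by
`uniroot` on `Σ p_i p_j e^{λ s_ij} = 1` (λ = ln 3 for uniform composition
with +1/−1) and K fixed at the documented constant 0.333; the default
score floor is the smallest integer S with E ≤ 1e-10 for the given query
and reference lengths. E-values and bit scores are emitted in the
outfmt6-compatible table so real BLAST output can be substituted.

## What the simulator emulates — and what it does not

`simulate_genome()` builds one main contig: a unique background into
which dispersed repeat copies (and tandem arrays, as single blocks) are
placed uniformly at random without overlap by rejection sampling (an
error, not silent degradation, if placement is infeasible). Each copy is
an independently mutated instance of the family consensus (per-base
substitution probability = `divergence`). Reads are placed uniformly with
i.i.d. substitution errors; true origins are recorded, so exact pileups
are available without an external mapper, and `project_depth()` folds a
true-genome pileup onto the collapsed assembly through its coordinate map
— i.e. the depth profile a perfect mapper would produce against the
collapsed assembly.

Deliberately absent: indels (substitution-only errors keep the alignment
oracles exact), GC-bias in read sampling, quality-score modelling,
structural variation, and diploid phasing (a `diploid_copy()` helper
duplicates the genome with a stated heterozygous substitution rate for
spectrum experiments, but simulation is haploid by default, matching the
assumption that modal coverage represents diploid coverage). A green test
on this generator therefore establishes the estimators' algebra and their
behaviour under repeat collapse — not robustness to mapping ambiguity,
coverage bias, or indel-rich platforms.

The repeat-rich default configuration (60% repeats: dispersed 5 kb × 40,
2 kb × 100, 500 bp × 200 per Mb, plus one 50 bp × 2000 tandem array, all
at 1% divergence) was chosen once as a plausible TE-plus-satellite mix for
an arthropod-like genome; the true repeat-family size distribution of any
real genome is unknown to this package and the defaults are illustrative.
Random sequential placement jams near ~75% linear fill, so repeat
fractions much above 60–65% in a single contig will exhaust the placement
budget by design.

## Numerical choices

- **Rounding.** Reported pg/Gb values round half-away-from-zero to 2
  decimals and SEMs to 3, because that convention reproduces every
  printed Gb cell of the reference FCM table from its pg cells;
  base R's `round()` (half-to-even) does not. Exact values are available
  everywhere via `round_digits = NA`.
- **CV** is computed on raw FL/IOD values, not on converted pg; the unit
  of replication for cross-group summaries is the specimen, not the
  nucleus (pseudoreplication guard). Hypothesis tests are not
  re-implemented; the module emits tidy tables for any stats package.
- **Mode discretisation.** Both estimators divide by an integer mode, so
  their relative error is bounded below by ~1/(2·mode); near-integer
  expected modes (e.g. `C (L − k + 1)/L` exactly 16) sit on a tie whose
  resolution flips the estimate by 1/mode. Test scales are chosen so the
  ±1-bin jitter stays inside the 5% recovery band; at very low modal
  depths (≤5) the discretised mode is unstable and high-side size
  estimates are expected.
- **Tie-breaks.** Modal peaks break toward the smaller multiplicity/depth;
  alignments rank by (score desc, reference position asc) independent of
  hash iteration order; alignments overlapping a better one by >50% on
  the reference are suppressed.
- **Coordinates.** Intervals are 1-based closed internally (the R/IRanges
  convention); BED output is converted to 0-based half-open and depth TSVs
  use 1-based positions, matching the `samtools depth` dialect (sparse
  positions are depth 0).

## Open design points, resolved

- The congruence statistic is ambiguous in the field's usage between
  "percentage of reads that mapped" and "mean query cover %"; both are
  computed (`mapped_fraction`, `mean_query_cover_pct`) and the matrix
  cells display mean query cover with the >95%-identity fraction in
  parentheses.
- The E-value contract allows a raw-score-floor fallback; the full
  Karlin–Altschul route was implemented since λ is one `uniroot` call,
  and the floor is derived from it.
- Depth-0 assembly positions enter the depth sum (as 0) and are excluded
  from the mode.

## Limitations

The aligner is not a general-purpose BLAST replacement: no protein space,
no full gapped E-value statistics, heuristic seeding means an alignment
whose optimal path drifts more than ~32 diagonals or lacks any exact
11-mer seed can be missed (irrelevant at the divergence levels tested,
where scores are verified against a full dynamic-programming oracle). The
k-mer counter holds the spectrum in memory (fine to tens of millions of
distinct k-mers; not a disk-backed Jellyfish replacement). All estimator
validation is against the simulator's stated world; none of it certifies
performance on real libraries with mapping ambiguity or coverage bias.
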