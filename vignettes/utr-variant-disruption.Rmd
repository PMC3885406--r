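---
title: "Predicting regulatory disruption by UTR variants: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting regulatory disruption by UTR variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrsnv)
```

## The problem

Untranslated regions of mRNAs carry two broad classes of *cis*-regulatory
elements that a single-nucleotide variant (SNV) can silently disrupt: local
RNA secondary structure (stem-loops, SECIS-like elements, other structured
motifs) and microRNA target sites. `utrsnv` implements both predictions for
SNVs given in transcript coordinates, plus the downstream statistics that
ask whether the genes carrying predicted disruptive SNVs are enriched for
known cancer genes.

All coordinates in the package are transcript-space, 1-based, inclusive.
BED-like annotation files are the standard 0-based half-open dialect on
disk and are converted on read.

## Structure disruption (riboSNitch detection)

For each SNV, a window of ±`flank` nt (default 200) is cut from the
transcript, the alternate base is substituted, and both alleles are folded:
`compute_pair_probabilities()` runs the McCaskill inside–outside algorithm
over pseudoknot-free structures, producing the equilibrium base-pair
probability matrices $P^{WT}$ and $P^{MT}$.

Two complementary measures quantify the ensemble change over every local
region $[a, b]$ of the window (minimum length 10 nt):

* Euclidean distance, normalized by region length so scores are comparable
  across regions:
  $d(a,b) = \frac{1}{b-a+1}\sqrt{\sum_{a \le k < l \le b}
  (P^{WT}_{kl} - P^{MT}_{kl})^2}$, maximized over regions ($d_{max}$);
* Pearson correlation $r(a,b)$ of the positional pairing profiles
  $p_k = \sum_l P_{kl}$ over the region, minimized over regions
  ($r_{min}$). Regions where either profile slice has zero variance are
  non-evaluable and excluded.

The scan is exhaustive over all $O(n^2)$ regions using prefix sums; ties
are broken toward the longer region, then the smaller start, so results
are deterministic.

**Empirical p-values.** The null distribution for an SNV is built from
`k` random single substitutions in the same window (uniform over positions
and the three alternate bases, excluding the observed substitution), with
the plus-one convention $p = (1 + \#\{d^{null}_{max} \ge d_{max}\})/(k+1)$
(mirrored with $\le$ for $r_{min}$). This null was chosen because it is
self-contained and calibrated by construction: scoring random substitutions
against their own null yields approximately uniform p-values (the test
suite checks a Kolmogorov–Smirnov D below 0.1 at 200 replicates with
k = 199). The d-based and r-based candidate lists are each corrected with
Benjamini–Hochberg separately and then fused as a union of SNVs; both the
raw-p (p < 0.1) and the BH-passing flags are emitted, since either
convention may be wanted downstream. Confidence tiers follow the
two-threshold rule: *high* when both p-values are below 0.05, *medium*
when either is below 0.1.

**Linked variants.** For a disruptive SNV with a partner variant in
linkage disequilibrium within the window, `ld_haplotype_test()` applies
both substitutions jointly and re-derives the p-values. The null stays the
single-substitution null of the main stage, so the joint change is judged
on the same significance scale as the original call; a substitution-pair
null was rejected because it would multiply the rate of null draws hitting
the structured element and silently shift that scale. The pair is reported
as a structure-stabilizing haplotype when neither measure remains
significant at p < 0.1.

## The energy model

The bundled model is a simplified nearest-neighbor scheme: Watson–Crick
and G:U wobble pairs; Turner-like stacking energies for Watson–Crick
stacks with wobble-containing stacks collapsed to two representative
values; affine hairpin (`5.0 + 0.05·len` kcal/mol), interior/bulge
(`3.5 + 0.25·len`) and multiloop (`3.4 + 0.4·branches`) penalties; no
dangles, no special tetraloops; interior loops above 30 nt are disallowed
(standard convention); minimum hairpin loop 3 nt; temperature 310.15 K
(energies are standard free energies; the temperature only sets RT in the
Boltzmann weights). The conclusions of the analysis rest on *differences*
between wild-type and mutant ensembles, which are robust to the simplified
parameterization; the model is pluggable (`energy_model()`,
`read_energy_model()`) so a full Turner-parameter backend can be swapped
in without changing any downstream contract.

Correctness of the $O(n^3)$ inside–outside implementation is established
against an independent oracle: `enumerate_structures()` enumerates every
pseudoknot-free structure of sequences up to 20 nt in pure R, Boltzmann-
weights each by its loop-decomposition energy, and returns exact pair
probabilities. The dynamic program agrees with the oracle to within
1e-9 on random sequences under both the default and the all-zero energy
model (where probabilities reduce to uniform-ensemble counting, checked
against a Nussinov-style counting recursion).

## miRNA target-site changes

For each SNV a 61-mer (±30 nt) is extracted for both alleles and screened
against the miRNA set in a cascade:

1. **Seed-match change filter.** `find_seed_matches()` types every 8-nt
   register by the canonical seed classes — `7mer-1a` (Watson–Crick match
   to miRNA positions 2–7 plus an adenosine opposite position 1),
   `7mer-m8` (match to 2–8), `8mer-1a` (both), in increasing strength;
   G:U pairs never count as seed matches. Only (SNV, miRNA) pairs whose
   (register, type) pattern differs between alleles continue.
2. **Duplex scoring.** `scan_duplex()` performs an anchored antiparallel
   gapped alignment per register (Watson–Crick +5, G:U +1, mismatch −3,
   gap open −9 / extend −4), with columns opposite miRNA positions 2–8
   weighted by `scale` (default 2: the seed is deliberately not
   over-weighted, since a seed change has already been required).
   Sites need score ≥ 45 and energy ≤ −5 kcal/mol (relaxed cutoffs, so
   compensated poor seed matches are retained). The reported energy is
   that of the energetically best contiguous block of paired columns —
   stacking terms over consecutive paired columns, affine interior/bulge
   penalties between them, plus a duplex-initiation term from the same
   energy model as the folding stage — so distant weak matches picked up
   by the score alignment do not dilute a site's energy.
3. **Strongest differing site.** Sites are paired by register (the
   subsequence position opposite miRNA position 1; substitutions keep the
   frames aligned). Among differing registers, the site minimizing
   min(ΔG_WT, ΔG_SNV) is retained.
4. **Classification** at the conservative working threshold −11 kcal/mol:
   *create* (site only in the mutant), *destroy* (only in the wild type),
   *alter* (both, at least one ≤ −11). For alter candidates the change is
   summarized as $lr = \log_2(\Delta G_{SNV} / \Delta G_{WT})$ (0 = no
   change; negative = wild type binds more strongly); base 2 is used for
   the log-ratio, which only scales the threshold below.
5. **Filters.** Destroy/alter candidates must lie inside an Ago CLIP
   cluster with biological complexity ≥ 2 (create candidates pass through:
   CLIP evidence exists for the wild type only); alter candidates must
   have |lr| strictly above the mean |lr| of the run's alter set (the mean
   is computed after the CLIP filter by default, matching the cascade
   order; a config flag computes it before); finally miRNAs are filtered
   for expression in the tissue of interest. Per-stage in/out counts are
   recorded and are monotone non-increasing.

## Enrichment statistics

`fisher_one_sided()` computes the upper-tail hypergeometric probability of
a 2×2 table with log-factorials; it is verified exhaustively against
brute-force hypergeometric summation for every table with total count ≤ 30
and cross-checked against `stats::fisher.test`. Gene-level enrichment
classifies the gene universe by carries/does-not-carry a disruptive SNV ×
cancer-associated/other; the SNV-level variant uses SNVs as units. The
one-sided direction is fixed to enrichment. Being an exact test, its null
p-values are valid but conservative (discrete), which is what the
calibration tests assert. Gene-level outputs collapse isoforms by gene
symbol and count unique (gene, SNV) pairs; this deduplication convention
is recorded in the run metadata.

## The synthetic benchmark

No real tumor transcriptome data ship with the package; a seeded generator
(`simulate_dataset()`) produces inputs with the statistical structure the
pipeline assumes, together with a ground-truth ledger:

* **Transcripts** (default 60 genes, one isoform each): 5' UTR 60–100 nt,
  coding filler 90 nt, 3' UTR 280–360 nt, background GC drawn from
  40–60%.
* **Hairpins**: one perfect stem-loop per 3' UTR, stem 5–6 bp at a fixed
  ~60% GC composition, loop 4–7 nt, flanked by 50-nt AU-rich quiet zones
  so the hairpin is the dominant structure of its folding window. Each
  plant is verified by folding (mean stem pair probability > 0.5 in a
  local window) and redrawn up to ten times: a stem of this size is
  strong enough to dominate its local ensemble yet weak enough that one
  broken pair collapses it outright (longer stems survive a single break
  as two sub-helices around an interior loop). The quiet zones matter
  because the
  length-normalized distance measure rates the toggling of a marginal
  background helix over a 10-nt region as highly as a full stem collapse;
  without them the null distribution of random substitutions in a 40–60%
  GC window is heavy-tailed enough to mask genuine breaks.
* **SNVs** (default 80): 30% stem-breakers — candidate substitutions
  (stem positions, alternate bases that can pair with the partner by
  neither Watson–Crick nor wobble rules) are folded in the local window
  and the one the disruption measure sees most strongly (largest d_max)
  is planted; 10% each of create/destroy/alter seed-site events; the rest
  neutral background substitutions at least 50 nt from any plant.
* **Target-site boxes**: one 22-nt box per 3' UTR with a fixed,
  non-repetitive GC-rich seed complement (`GCGGCGC` facing miRNA
  positions 8–2), the 1a adenosine, an AU guard, and 10-nt AU-rich quiet
  zones on both sides; the hairpin sits 28 nt away so it stays outside
  the 61-mer. Destroy/create SNVs hit mid-seed (opposite miRNA position
  5) with allele constraints that rule out wobble retention; alter SNVs
  hit the m8 position and their miRNAs carry an additional 3'
  supplementary patch so both alleles keep a working site.
* **miRNAs**: one per site event — random body, complementary seed — plus
  shuffled decoys up to `n_mirnas`. Each planted event is verified against
  the actual cascade (the classification must come out as intended) with
  the body redrawn up to 25 times; accidental complementarity of a random
  body is the only failure mode this removes.
* **Annotations**: conserved-structure intervals over the planted
  hairpins; CLIP clusters covering planted wild-type sites with
  configurable probability and BC ~ 1 + Poisson(2); cancer labels drawn so
  disruptive-SNV genes have a configurable enrichment odds ratio
  (default 1.2, roughly the effect size the gene-level statistics target);
  expressed/lung-cancer/NSCLC miRNA lists.

Everything is deterministic given `rng_seed`, and the generator's files
are byte-valid inputs for the package readers.

**What the benchmark does and does not show.** Passing the planted-signal
checks demonstrates that the pipeline recovers structure-breaking and
seed-changing substitutions it was designed to detect, at the stated
false-positive level, on sequences whose background is random. Real UTRs
are not random: they carry composition bias, repeats, paralogy, RNA
editing and expression-coupled variant calling artifacts, none of which
the generator emulates; sequencing error, allele frequencies, and
somatic/germ-line mixtures are deliberately out of scope. Benchmark
results therefore bound the method's behavior under its own model
assumptions, not its accuracy on tumor data.

## Problem sizes and numerical choices

The bundled benchmark runs the structure stage at flank 80 with k = 199
null substitutions per SNV, and the calibration study on 61-nt windows
(200 replicates, k = 199); these sizes give stable rates from a single
seeded run. Full-scale analyses use the defaults: flank 200 and k = 1000.
Other conventions: scan tie-breaks (longer region, then smaller start);
zero-variance profile slices excluded from $r_{min}$; windows containing
non-ACGU characters skipped with a logged count; sequences shorter than
`min_hairpin + 2` flagged rather than folded; p-values reported to three
decimals in tables and at full precision in machine output.

## Known limitations

* The folding model is intentionally simplified; absolute energies are
  approximate even though ensemble differences are well-behaved. A Turner
  backend can be plugged in via `energy_model()`.
* The duplex aligner's score constants are standard miRanda-family values,
  but the exact published constants of that family are not fixed by a
  single source; all constants live in `default_duplex_params()` and in
  the run metadata.
* The empirical null resamples point mutations in the same window, not a
  GC/length-matched background of foreign sequences; p-values are
  calibrated against that null only.
* Pathway/network analysis of candidate genes is out of scope; the
  pipeline exports plain gene lists for external tools.
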