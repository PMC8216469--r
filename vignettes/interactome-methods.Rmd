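---
title: "Calling sRNA interactions from proximity-ligation chimeras: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling sRNA interactions from proximity-ligation chimeras: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligrkit)
library(data.table)
```

## The problem

In vivo psoralen (AMT) crosslinking followed by proximity ligation and
sequencing captures RNA–RNA duplexes as *chimeric reads*: single reads whose
two halves map to two different places in the genome. In a bacterium this is
a direct, hypothesis-free way to find the targets of small regulatory RNAs
(sRNAs) — including RNA *sponges*, sRNAs whose job is to sequester other
sRNAs. The hard part is statistical, not biochemical: ligation also joins
random neighbouring RNAs, at a rate driven by abundance, so a raw chimera
count means nothing until it is compared against what random ligation would
produce for that particular pair of transcripts.

`ligrkit` implements that analysis end to end: classification of aligned
chimeric reads against an annotation, construction of replicate-merged
interaction count matrices, a one-sided hypergeometric enrichment test per
pair with Benjamini–Hochberg FDR control, and extraction of sequence windows
for downstream hybridization predictors. It also implements the quantitative
bench assays that accompany such a study: rifampicin-chase half-life
estimation, gel standard curves, absolute quantification against in vitro
standards, plate-reader promoter activity, and competition fitness tests.

A first-class synthetic-data generator produces a toy genome, a ligation
library with *planted* interactions, and per-read truth tables, so every
stage of the pipeline is testable without any external download.

## Read classification

Alignments arrive as SAM records (primary plus supplementary segments
grouped by read name); the toy split aligner in the package produces the
same structure. Each segment is assigned to the feature with **maximal
overlap**; ties go to the smaller feature, then to the lexicographically
smaller id. Strand is ignored in assignment — the recovered orientation of a
crosslinked duplex carries no usable information in this protocol, and
coordinates are 1-based inclusive throughout (GFF3/SAM convention).

Because many fragments fall outside the annotation, the complement of the
annotated intervals is tiled with **UA features** (`UA-<start>-<stop>`,
unstranded) before assignment, so every position belongs to some feature.
Complement intervals shorter than `min_ua_length` (default 30 nt, below any
realistic fragment) are skipped; with `min_ua_length = 1` the tiling is
exact, which is how the tiling property is verified in the tests.

Every read receives exactly one class:

| class | rule |
|---|---|
| `repeat_ambiguous` | any segment without a unique placement |
| `intramolecular` | two segments, one feature |
| `junction_artifact` | two features overlapping or nearly adjacent (gap ≤ 50 nt) |
| `proximal_excluded` | distinct features with closest-edge gap ≤ 2000 nt |
| `interaction` | distinct features separated by > 2000 nt |
| `unassigned` | no chimeric junction (single segment), or > 2 segments |

The 2000 nt proximity filter removes local artefacts (read-through,
neighbouring-operon ligation) at the cost of genuine *cis* contacts; it is
the assay's own operating definition of a trans interaction. The separation
is computed edge-to-edge between the *features* (not the segments), before
replicate merging, and optionally on a circular chromosome
(`min(linear gap, wrap-around gap)`), as appropriate for a bacterial
genome. The junction/proximal boundary at 50 nt separates reads that could
plausibly span a junction between adjacent transcripts from merely nearby
pairs; only the 2000 nt threshold affects what is *tested*, since both
intermediate classes are excluded from the interaction matrix.

Multi-hit (repeat-derived) placements are discarded as `repeat_ambiguous`
rather than randomly placed: with a hypergeometric test downstream, a wrong
deterministic assignment is worse than a lost read.

## The enrichment model

For a merged matrix with total interaction count $N$, a pair $(A, B)$ with
chimera count $k$ and per-feature totals $K = K_A$ and $n = K_B$ (each
including $k$ itself) is scored with the upper-tail hypergeometric
probability

$$P = \Pr(X \ge k), \qquad X \sim \mathrm{Hypergeometric}(N, K, n),$$

i.e. the chance that drawing $B$'s $n$ interaction reads from the library
would hit reads involving $A$ at least $k$ times. The test conditions on
both marginals, which is exactly what absorbs abundance-driven background:
an abundant transcript has large marginals, and large pair counts are then
expected rather than surprising. Only the upper tail is tested — depletion
of a ligation product is not biologically interpretable here. Self pairs
never occur ($A$–$A$ reads are intramolecular by construction), and $N$
counts interaction-class reads only, not intramolecular or non-chimeric
reads.

The tail is accumulated in log space from log-factorials and is exact: the
test suite checks every tuple with $N \le 30$ against direct enumeration
(agreement to $10^{-10}$; observed $\sim 10^{-14}$) and random large tuples
against an independent distribution-function implementation.

Raw p-values below 0.05 define the permissive "significant" set; the
confident set applies Benjamini–Hochberg step-up control at FDR 0.05
($q_i = p_i\,m/i$ on the sorted vector, monotonized from the top, capped at
1). Both sets are reported, the FDR set always nested in the raw set. Pairs
are tested from one chimera upwards by default (`min_count`), since the
paper-style analysis states no floor; the BH adjustment spans all tested
pairs.

Two deliberate ambiguities are exposed as switches rather than silently
decided: whether $N$ should instead count all reads of the sample (our
default: interaction reads only — the conditioning is cleaner and the
alternative only makes every test more conservative), and whether the pair's
own count should be subtracted from the marginals (not done; marginals
include $k$).

## The synthetic library

The generator emulates the study design rather than any particular dataset:

* **Genome**: `n_genes` CDS plus `n_srnas` sRNA features placed
  non-overlapping with at least `min_gap` nt between them on a random
  sequence; no 20-mer repeats on either strand outside an optional flagged
  repeat block, so the exact-match toy aligner is unambiguous by
  construction, and repeat reads are ambiguous by construction.
* **Abundances**: log-normal per-feature weights (default meanlog 0,
  sdlog 1) — heavy-tailed expression is the feature of real libraries that
  the enrichment test must absorb.
* **Reads**: per replicate, `n_reads` single-end reads split into
  non-chimeric reads (feature drawn $\propto a_i$), intramolecular chimeras
  ($\propto a_i^2$, the pair-model applied to self pairs), and
  intermolecular chimeras: pair $(i,j)$ drawn $\propto a_i a_j e_{ij}$ with
  $e_{ij}$ = the configured enrichment fold for *planted* pairs and 1
  otherwise. Fragment positions are uniform within features, lengths uniform
  in `fragment_length_range` (default 25–60 nt; the post-digestion fragment
  size distribution is not documented for this protocol, so it is a free
  knob), and the order of the two fragments in a read is randomized —
  ligation orientation is unknowable, so everything downstream must be
  order-invariant (and is tested to be).
* **Planted pairs** default to sRNA partners with at least median abundance
  separated by more than 2000 nt: they stand for genuine trans interactions
  of expressed sRNAs, the class the assay is designed to detect. A "planted"
  pair below either bar would be undetectable by construction — not because
  the test lacks power, but because the library (low abundance) or the
  filter (cis proximity) never shows it.
* **Replicates** use seed + replicate-index streams; two replicates by
  default, summed before testing, as in the assay design. Qualities are
  constant `'I'` and unused.

What the generator does *not* model: sequencing errors, adapters, rRNA
contamination, paired-end mates, transcription units spanning several
features, or position-dependent ligation efficiency. Passing the planted
recovery test therefore shows the inference machinery is correct and
calibrated under abundance-driven background — it does not certify
performance on real libraries, where mapping noise and structural biases
add false pairs that only the proximity filter and FDR control mitigate.

Truth tables accompany every simulated read, and `emit_truth_alignments()`
converts them into alignment segments directly (bypassing sequence
alignment), giving a noise-free route used to prove exact end-to-end count
conservation. The toy aligner itself finds the longest exact-match prefix
and suffix of each read (both strands, 20 nt anchor seeds); on noise-free
reads its only deviation from truth is a few nucleotides of chance
over-extension across the ligation junction, which never changes a feature
assignment and is tested as such.

## Kinetics computations

**Half-lives.** A rifampicin chase blocks transcription initiation; band
intensities, normalized to a stable loading control (16S/5S rRNA) and to the
time-zero value, give percent-remaining curves. The fit is ordinary least
squares of $\log_{10}(\%\,\mathrm{remaining})$ on time, and
$t_{1/2} = -\log_{10}(2)/\mathrm{slope}$ — note the printed formula only
holds on the log10 scale, which is why the package never fits natural-log
decay. Some RNAs decay biphasically (two co-existing populations, e.g. a
sponge-bound and a free pool); the reported half-life then comes from the
*initial* slope. Since eyeballing biphasic curves is not reproducible, model
selection is automated: every interior breakpoint with at least three
points per segment (shared knot) is tried, the best two-segment fit is kept,
and `auto` accepts it only when it lowers the BIC with the breakpoint
counted as a parameter *and* improves the SSE beyond numerical noise
($10^{-10}(\mathrm{SST}+1)$ — so exactly log-linear data always stay
monophasic). Flat or slow series are censored and printed as `> t_max`
(default: the last sampled time), never extrapolated to a number beyond the
sampled range. Replicates are averaged point-wise on the percent scale
before fitting; fitting per replicate and averaging half-lives is the main
alternative, and with duplicate blots neither is clearly better — the
averaged-curve choice matches how such figures report "average of two
experiments" with per-point deviations.

**Gel sizing and absolute quantification.** Ladder migration gives an OLS
standard curve of $\log_{10}(\mathrm{size})$ vs distance; sample sizes are
read off within the ladder range only (no extrapolation). Known fmol
amounts of in vitro transcript give an intensity-vs-fmol line; sample
intensities are inverse-regressed, again only within the calibrated range.

**Promoter activity.** Plate-reader series yield
$a_t = (\mathrm{GFP}_t - \mathrm{GFP}_{t-1}) / \mathrm{OD}_{600,t}$ after
subtracting the time-matched fluorescence of an isogenic non-GFP control
(negative values floored at zero with a warning), then a centered 3-point
moving average whose window shrinks at the series edges.

**Competition fitness.** Per-replicate CFU ratios from a 1:1 co-culture,
normalized by the verified inoculum ratio, are compared between strains
with Welch's unequal-variance two-sided t-test (Satterthwaite degrees of
freedom). Ratios are tested untransformed by default with a `log_ratios`
switch, and biological-replicate values are what enter the test.

## Numerical and design notes

* Hypergeometric tails: log-space summation over the support, capped at 1;
  tolerance against enumeration $10^{-10}$ for $N \le 30$.
* BH: step-up with cummin from the top; matches the reference
  implementation to $10^{-12}$ on 1000 random vectors in the tests.
* Tie-breaks in assignment (smaller feature, then id) make the pipeline
  deterministic; determinism of the generator is byte-level on FASTA/GFF3
  outputs for a fixed config.
* Degenerate inputs: empty SAM files, empty annotations, fully annotated
  chromosomes, features shorter than the minimum fragment length (skipped
  with a warning), zero-variance Welch inputs (identical groups return
  $t=0, p=1$), and flat decay series (censored) are all defined behaviour
  with tests.
* Problem sizes in the checks: the planted-recovery and null-calibration
  properties run at 200 features, $10^5$ chimeric reads across two
  replicates, five planted pairs at 20-fold enrichment, repeated over 20
  seeds in the test suite (10 in the acceptance script); these sizes give
  expected planted counts of tens to hundreds of chimeras, comfortably
  separated from single-digit background pairs, while the whole suite stays
  desk-scale.

## A worked miniature

```{r example}
cfg <- sim_config(genome_length = 60000, n_genes = 30, n_srnas = 5,
                  n_reads = 8000, frac_chimeric = 0.7,
                  frac_intramolecular_of_chimeric = 0.2,
                  min_gap = 150, seed = 42)
g <- generate_genome(cfg)
ab <- sim_abundances(cfg, g$features)
cfg$planted_pairs <- plant_random_pairs(g$features, ab, 2, fold = 30, seed = 42)
cfg$planted_pairs

sim <- simulate_ligation(g, ab, cfg)
ft <- make_ua_features(g$features, g$chrom_lengths)
aln <- lapply(sim$replicates, function(r) emit_truth_alignments(r$truth, ft))
run <- call_interactions_end_to_end(gff = g$features,
                                    chrom_lengths = g$chrom_lengths,
                                    alignments = aln)
run
head(run$significant$fdr[, .(featureA, featureB, k, K, n, N, p_raw, p_adj)])
```

Both planted pairs surface at the top of the FDR set; the background pairs
tested alongside them stay flat. A half-life fit on a synthetic biphasic
chase shows the kinetics side:

```{r decay}
tt <- c(0, 2, 4, 6, 8, 10, 15, 20, 25, 30)
pm <- ifelse(tt <= 10, 100 * 2^(-tt / 5), 25 * 2^(-(tt - 10) / 10))
fit_halflife(data.table(time = tt, percent_remaining = pm), model = "auto")
```

## Known limitations

* The aligner is an exact-match toy for synthetic genomes; real libraries
  should be aligned with a chimera-aware aligner and ingested via
  `read_sam_alignments()`.
* The distance filter discards genuine cis interactions below 2 kb by
  design; nothing in the package recovers them.
* Hybridization prediction itself (IntaRNA-class tools) is out of scope;
  the package only builds their input windows (UTR-extended span, else
  ±50 nt flanks).
* The hypergeometric model conditions on marginals and assumes exchangeable
  background ligation; systematic ligation biases (structure, position)
  would require a calibrated null beyond abundance.
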