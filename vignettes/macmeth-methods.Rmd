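---
title: "Methods: paired differential methylation analysis with macmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired differential methylation analysis with macmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Monocytes differentiate into macrophages within days, and macrophages can
be further activated toward pro-inflammatory, anti-inflammatory or
foam-cell states. `macmeth` implements a desk-scale pipeline for asking how
DNA methylation is remodeled across this differentiation and activation
axis when the same donors are profiled in every cell state: which CpGs
change (and in which direction), which cell state drives each change,
whether the changes are confined to single CpGs or extend over regions,
and what regulatory context (chromatin states, open chromatin, enhancers,
transcription-factor binding sites) they occupy.

## The per-CpG model

For one CpG, let `y_dc` be the methylation beta value of donor `d` in cell
state `c` (n donors, k states; the default design is 4 donors by 6 states:
monocyte, naive macrophage, and macrophages activated with LPS/IFN-gamma,
IL-4, oxLDL or acLDL). The working model is a donor random-intercept model,

```
y_dc = mu + s_c + a_d + e_dc,   a_d ~ N(0, sigma_a^2),  e_dc ~ N(0, sigma^2)
```

fitted per CpG. For a balanced complete table this model's F test of the
cell-state effect is *exactly* the two-way within-donor ANOVA:

* `SS_state = n * sum_c (m_c - m)^2`, `ms = SS_state / (k - 1)` — `ms` is
  the "mean squares" effect-size criterion;
* `F = ms / MS_res` with df `(k - 1, (k - 1)(n - 1))`;
* per-state partial t statistics
  `t_c = (m_c - m) / sqrt(MS_res (k - 1) / (n k))`.

`macmeth` therefore implements the closed-form ANOVA rather than iterative
REML: it is deterministic, oracle-testable, and identical to the
REML route (with Satterthwaite denominator df, which are exact here)
whenever the donor-variance estimate is interior. The equivalence is
property-tested against `lmerTest`; it genuinely breaks only when REML
estimates the donor variance at the zero boundary, which the balanced
F test does not suffer from. Unbalanced data are handled by complete-case
donor exclusion per CpG (fewer than 3 complete donors skips the CpG with a
reason), not by approximation.

A CpG is a DMC when `q < 0.05` (Benjamini–Hochberg across tested CpGs) and
`ms > 0.0025`. The mean-squares cutoff corresponds to a 5 percentage-point
difference when only two conditions are compared; both thresholds are
configurable. One published description of this analysis prints the cutoff
as 0.025 in one place and 0.0025 elsewhere; `macmeth` uses 0.0025, the
value given wherever the threshold is actually defined.

**Attribution.** The cell state contributing most is the argmax of
`|t_c|`, computed on the state-mean deviations (within a CpG the partial
t's are proportional to the deviations, and deviations stay defined for
degenerate zero-residual CpGs): monocyte means a differentiation DMC, the
naive macrophage a macrophage-specific DMC, an activated subtype an
activation DMC. When a second state reaches 90% of the top deviation the
CpG is labelled `multi`. The partial-t definition (deviation from the
grand mean over its standard error) is one reasonable convention —
the statistic is named but not defined in the analyses this package
re-implements — and is configurable in spirit: all ingredients are in the
output table. Exact argmax ties are resolved by the fixed state order and
counted.

**Direction.** `delta_beta` is mean(macrophage-derived states) −
mean(monocyte) for differentiation/multi DMCs, macrophage − monocyte for
macrophage-specific ones, and subtype − naive macrophage for activation
DMCs; gain means `delta_beta > 0`.

**A monotonicity caveat.** With noise held fixed, F as a function of a
planted effect size is a quadratic over a constant, so it is increasing
only beyond a vertex of order `noise_sd / sqrt(n)`; the property tests
check monotonicity above that scale.

## Enrichment machinery

All enrichment questions use one uniform object: a 2x2 table
(target/background x feature/not) with the sample odds ratio
`(a d)/(b c)` and a two-sided Fisher p computed by the probability-mass
convention (the sum of hypergeometric probabilities of tables no more
likely than the observed one, with the customary `1 + 1e-7` relative
slack). Reported p values are additionally floored at `2.2e-16`
(`p_capped`), the smallest accurately representable value, with the raw p
retained. Infinite and zero odds ratios are reported as-is with flags; a
Haldane–Anscombe (+0.5) helper exists for plotting only. Within each
enrichment family, BH correction is applied across strata.

Backgrounds default to all measured non-DMC CpGs: in this artifact only
measured positions carry annotation calls, so "genome-wide" comparisons
are taken at measured positions, with targets excluded from the
background.

The gain-over-loss transition grid tests, for each monocyte-to-macrophage
chromatin-state transition, whether gain-DMCs occupy it more than
loss-DMCs (`OR > 1` = gain-enriched, drawn in log2). The TF-binding-gain
test restricts to CpGs whose motif window contains a given motif and asks
whether gain-DMCs acquire a ChIP peak (peak in macrophage, none in
monocyte) more often than background CpGs at the same motif. The
expression-shift test takes the nearest genes of gain- and loss-DMCs and
applies a Wilcoxon signed-rank test to paired macrophage − monocyte logTPM
differences: exact (doubled smaller tail of the signed-rank distribution,
equivalent to enumerating sign assignments) for n ≤ 25 without ties,
normal approximation with continuity and tie corrections otherwise; all
zero differences give p = 1 by convention.

## Annotation conventions

Interval tracks are 0-based half-open internally (BED convention); CpG
positions are 1-based cytosine positions converted exactly once at the
overlap boundary, so a CpG at position p overlaps `[start, end)` iff
`start <= p - 1 < end`. Probe strand is ignored for overlaps (the site
collapses to its cytosine position); motif scanning handles strand
itself.

Chromatin-state consensus is computed per CpG position — a majority vote
among donors' state labels at that base pair (default: at least 3 of 5
donors) — rather than per segment, avoiding segment-boundary
reconciliation. DNaseI hypersensitivity uses per-cell-type vote
thresholds (defaults 3 of 5 donor tracks in monocytes, 2 of 4 in
macrophages; both configurable, mirroring designs where the two cell
types have very different donor counts). Ambiguous majorities (possible
when `min_votes <= donors/2`) are no-calls, flagged. Nearest genes
minimize the distance to any transcription start or end site — the two
points exactly, not gene bodies — with ties broken toward a TSS, then
lexicographically, and counted.

## WGBS integration and DMR demarcation

Array DMCs are mapped to WGBS by exact position; "sufficiently covered"
means present in both cell-type tracks with at least 3 donors each (the
sufficiency threshold is an artifact convention — the underlying analyses
never quantify it). A covered DMC is *concordant* when the WGBS
difference has the array direction and at least 5 percentage points of
magnitude. Around each concordant seed, the DMR is the maximal run of
consecutive covered WGBS CpGs where every member keeps `|delta| >= 0.05`
with the seed's sign and consecutive members lie within `max_gap` bp;
extension stops at the first failure per direction (the strictest reading
of a seed-and-extend rule; skipping non-qualifying CpGs is not allowed).
Uncovered WGBS CpGs are not measurements and are invisible to the run
(the gap rule still applies across them). `max_gap` defaults to 1,000 bp;
the literal megabase variant that appears in print is selectable but a
1 Mb gap inside a DMR is treated as implausible. A single-CpG DMR has
length 1 bp; the median DMR length statistic depends on this convention.

Concordance enrichment compares the concordance rate of DMCs against
non-DMCs (fold ratio plus Fisher p on covered CpGs).

## Threshold sensitivity

The sensitivity stage splits the covered-and-concordant DMC set by WGBS
effect size (>5%, 5–30% closed on both ends, >30% strict — boundary
inclusion is documented because published descriptions do not state it)
and by DMR size (≤4 vs >4 CpGs), separately for gain and loss, and
reports retained counts and lost fractions. Effect size uses the WGBS
delta at the seed CpG (an array-delta mode exists), since thresholds are
applied to DMCs sufficiently measured in WGBS. Enrichments (chromatin
states, DNaseI change, top motifs) are re-run per retained subset when at
least 20 DMCs remain, aligned for side-by-side comparison.

## The synthetic study generator

The generator produces every pipeline input plus a ground-truth table, so
each stage is testable without downloads. What it emulates, and the
default study conditions:

* **Design**: 4 donors x 6 states, one sample per donor/state; 10,000
  CpGs on one synthetic chromosome (uniform 400–800 bp spacing).
* **Betas**: `clamp(mu_i + a_id + e_ic + eps, 0, 1)` with bimodal
  baselines (Beta(0.6, 0.6), spanning ~0–1), donor SD 0.05, noise SD
  0.03. Clamped Gaussian noise, not logit-normal: simpler and adequate
  for rank/threshold behavior; the clamped fraction is reported.
* **Planted effects**: 1,200 gain and 800 loss differentiation DMCs;
  rare, loss-dominated activation effects (LPS/IFN-gamma dominant) and a
  handful of macrophage-specific DMCs. Gains carry smaller effects
  (|delta| ~ U(0.10, 0.25)) in shorter regions (2–4 WGBS CpGs) than
  losses (U(0.30, 0.50), 5–9 CpGs). This asymmetry is the designed
  condition behind the threshold-sensitivity conclusions: stringent
  effect-size and region-size cutoffs should eliminate nearly all gains
  while sparing most losses. The gain:loss ratio (1.5) keeps gain
  dominance while leaving enough losses for stable stratified
  re-enrichment at desk scale. Planted baselines are (re)drawn inside
  the clamp margin so every effect is feasible; region members share the
  seed's baseline regime for the same reason.
* **WGBS**: geometric inter-CpG spacing (mean 40 bp) including all array
  positions; 78% of array CpGs sufficiently covered; a planted effect is
  expressed in WGBS with probability 0.5 (array-specific signal exists),
  spanning its region with the planted sign, 26% of expressed effects
  confined to a single CpG; background CpGs carry a random-direction
  difference of at least 5 points with probability 0.10, so non-DMC
  concordance sits near 5% and the DMC/non-DMC fold lands near 10.
  The CpG on either side of a planted region carries no difference, so
  realized region geometry equals the planted geometry and the
  single-CpG fraction of recovered DMRs estimates the configured value
  directly.
* **Annotation**: per-CpG consensus states with donor concordance 0.9
  (a free parameter — no published inter-donor concordance exists to
  anchor it); planted loss-DMCs sit at activating transitions
  (enhancer to active enhancer, quiescent to enhancer), planted gains at
  repressed or repressive transitions; DNaseI changes at 60% of losses
  and 30% of gains versus ~3% background; Hi-C enhancer intervals at 30%
  of DMCs versus 15% background.
* **Motifs and ChIP**: a random uniform genome with motif consensus
  sequences written into the windows of planted DMCs (CEBP-like at 50%
  and ETS-like at 35% of gains; AP1-like at 50% of losses; 2% background
  per motif) plus three decoy motifs; ChIP binding gain at 60% of
  gain-DMC motif sites against a 9% background, putting the expected
  binding-gain odds ratio in the mid-teens.
* **Expression**: genes tile the genome every 3 kb so each CpG has a
  nearest gene; genes nearest to loss-DMCs gain ~1 logTPM in macrophages,
  gain-DMC genes lose ~1.

What the generator does **not** emulate: probe chemistry and batch
effects, sex effects, mQTL structure, GC-matched motif backgrounds,
realistic chromatin-state segment geometry (states are per-CpG
segments), and read-level WGBS coverage. Passing tests therefore show
that the statistical machinery recovers planted structure under the
stated noise model — not that the pipeline is robust to array artifacts
or normalization choices, which are out of scope.

## Motif scanning

The known-motif step is a plain PWM scan, not a reimplementation of a
full motif suite: de novo discovery, ZOOPS scoring and GC-matched
backgrounds are deliberately absent. Windows of ±25 bp around each CpG
(a "50 bp window", read as total width; configurable) are scored on both
strands with pseudocount-smoothed log2-odds (pseudocount 0.01, uniform
background); a hit requires 80% of the motif's maximum attainable score;
N bases contribute zero. Enrichment contrasts hit-containing windows of
DMCs against a seeded random sample of up to 50,000 non-DMC CpGs,
ranked by Fisher p.

## Numerical and degenerate-input choices

* Zero residual with a non-zero state effect (exact noise-free data)
  gives `F = Inf, p = 0`, flagged degenerate; an all-constant CpG gives
  `F = 0, p = 1` by convention. Detection uses a relative tolerance of
  100 machine epsilons on the sums of squares.
* `bh_fdr` validates inputs and delegates to the standard step-up
  implementation; tests pin it to the formula applied directly.
* Config serialization round-trips through YAML; a second serialization
  is byte-identical.
* All randomness flows from one seed; the pipeline run, including
  background sampling for motif enrichment, is deterministic per seed
  and re-runs byte-identically.

## Problem sizes used by the test-suite

The packaged checks run the default study (10,000 CpGs) across ten seeds
for the end-to-end properties, 5,000-CpG null studies across twenty
seeds for false-discovery control, and a 2,000-CpG study with 100
planted effects for power; the oracle comparisons use exhaustive
enumeration (all 2x2 tables with N ≤ 60, all sign assignments to n ≤ 10)
or brute-force search (1,000 random WGBS tracks). These sizes are the
package's choice of a desk-scale design point: large enough for stable
rates, small enough to iterate on quickly.

## Known limitations

* The balanced-ANOVA route requires complete donor-state tables per CpG;
  heavily unbalanced designs lose donors rather than information-weighted
  precision.
* Consensus annotation is pointwise; segment-level state semantics
  (transitions within a segment) are not modeled.
* The motif stage's uniform-background scan will overstate enrichment of
  GC-rich motifs on GC-biased real genomes; on the synthetic uniform
  genome this does not arise.
* Headline numbers from any real study of this design (absolute DMC
  counts, specific odds ratios) depend on its data and are not
  reproduced by the synthetic defaults; the pipeline reproduces the
  qualitative architecture and all algorithmic properties.
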