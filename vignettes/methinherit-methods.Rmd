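---
title: "Models and methods behind methinherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methinherit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methinherit)
library(data.table)
```

`methinherit` analyses paternal epigenetic inheritance from replicated
whole-genome bisulfite sequencing (WGBS) count data: it calls
differentially methylated regions (DMRs) between a control and a
stressed group of sires, asks whether those differences persist in the
sperm of untreated sons (F1) and grandsons (F2), follows each region
through the embryonic reprogramming stages — inner cell mass (ICM,
E3.5), primitive streak (PS, E7.5) and primordial germ cells (PGC,
E13.5) — and relates the regions to differentially enriched sperm small
non-coding RNAs (sncRNAs) by sequence complementarity. This vignette
explains the statistical models, the default parameters and the design
decisions, and what the synthetic-data validation does and does not
demonstrate.

## Data model

The atomic observation is a CpG dinucleotide in one sample with a
methylated read count `mC` out of `total` reads; the methylation level
is $\beta = mC/total$. Counts on the two strands of a symmetric CpG are
summed onto the plus-strand C before any filtering, because the
analysis unit is the CpG dinucleotide and collapsing maximises usable
coverage. Whether collapsing should precede the coverage filter is not
externally fixed; collapsing-first is the default and
`collapse_strands = FALSE` preserves per-strand units. Only sites
covered at least fivefold enter any analysis, and missing sites are
absent records — never imputed zeros. Intervals are 0-based half-open
internally; Bismark-style inputs (1-based) are converted at the I/O
boundary only.

## DMR calling

The caller is a smoothed, dispersion-shrunk beta-binomial Wald test in
the tradition of DSS-style two-group comparisons, written for this
package:

1. **Smoothing.** Each group's replicate counts are pooled per site and
   smoothed with a 500 bp moving window (`span_bp`, the conventional
   smoothing span): a site's level becomes the coverage-weighted mean
   of the raw levels in the window, which equals the pooled-count level
   of the window. Methylation is locally correlated at this scale, so
   the windowed estimator borrows strength from neighbours.
2. **Dispersion.** For each site and group a method-of-moments
   beta-binomial dispersion is estimated from the replicate
   proportions, then shrunk toward the genome-wide mean dispersion with
   weight $(k-1)/(k-1+\nu)$ for $k$ covered replicates ($\nu =$
   `shrink_df`, default 4). With three replicates the raw estimate is
   nearly uninformative, so strong shrinkage is both intended and
   necessary; sites with fewer than two covered replicates take the
   prior mean.
3. **Wald test.** The statistic is $(\beta_{stress} -
   \beta_{control})/SE$, where each group's variance is the
   beta-binomial variance of its windowed pooled estimator given the
   shrunk dispersions and the actual per-replicate coverages in the
   window. The variance is floored at the binomial variance of one
   continuity-corrected pseudo-observation, so sites fixated at 0 or 1
   can never produce infinite statistics; identical groups are defined
   to give $p = 1$. Two-sided p-values use the normal reference and are
   Benjamini–Hochberg adjusted across all tested sites. (A classical
   local-FDR is approximated by BH here; the ranking is what the
   downstream thresholds consume.)
4. **DMCs and DMRs.** A site is a differentially methylated cytosine
   (DMC) iff $|\Delta\beta| > 0.1$ and FDR $< 0.01$. Same-direction
   DMCs within 100 bp (`merge_gap_bp`) are chained; an intervening
   tested CpG whose smoothed difference has the opposite sign severs
   the chain (the external description asks only for "similar
   methylation patterns", so the gap and the sign rule are explicit,
   configurable choices). A chain of ≥ 4 DMCs spanning ≥ 50 bp becomes
   a DMR.
5. **Post-filter.** Because merging admits non-significant CpGs, a
   region is kept only if $|\Delta\beta| \ge 0.1$ **or** its relative
   change exceeds 20%, with relative change defined as
   $|\Delta\beta| / \max(\beta_{control}, 0.01)$. The denominator floor
   is our reading of "varied by more than 20%": a region moving from
   essentially unmethylated to moderately methylated is a large change
   relative to its origin even when the absolute difference is small.

Null calibration (below) shows the combination of the variance floor,
shrinkage and the two-threshold DMC rule yields essentially no false
regions on effect-free synthetic methylomes.

## Inheritance classification

For every F0 DMR the region level of each sperm replicate (pooled
counts over covered sites) is compared between groups within each
generation by an unpaired Welch t-test on the 3 v 3 replicate levels
(Welch rather than pooled, because with three replicates per arm the
equal-variance assumption is untestable). A generation is *significant*
when the raw t-test p-value is below 0.05 **and** the difference passes
the same absolute-or-relative effect rule as the post-filter. The criteria are read as raw $p < 0.05$ on the per-generation t-test,
with FDR $< 0.01$ being the DMR-calling threshold the candidate
regions already satisfy: a BH-adjusted 1% threshold on a 3 v 3 t-test
has essentially zero power (the median adjusted value for true
attenuated effects exceeds 0.05), which would make every inheritance
class empty by construction. BH-adjusted values are still computed and
reported per generation, and `fdr_max` restores the stricter reading.

Labels follow the truth table: significant in F0, F1 and F2 →
*transgenerational*; in F0 and F1 only → *intergenerational*; in F0
only → *F0_only*; anything else (including uncallable generations) →
*irregular*. Direction consistency across generations is reported but
not required by default, because the classes are defined in terms of
"differentially methylated" alone; `strict_direction = TRUE` demotes
sign-flipping calls. Summary percentages report the *inherited* class
inclusively (transgenerational ⊂ inherited), matching the field's
"X%, of which Y%" phrasing.

The alternative route treats the three generations as paired
replicates: a one-tailed exact Wilcoxon signed-rank test on the
generation-mean pairs, tail fixed by the F0 direction, zeros excluded.
This route is structurally conservative — the exact one-sided p cannot
fall below $1/8$ at $n = 3$ or $1/4$ at $n = 2$ — so at stringent
thresholds it labels nothing inherited; it is retained as the
cross-check (the per-generation route is the more accurate of the two),
and both outputs are emitted rather than silently merged.

`delta_trend()` quantifies attenuation: mean $|\Delta\beta|$ per
generation over the heritable set, with one-sided paired t-tests that
the difference shrinks generation over generation.

## Embryonic reprogramming

Each DMR's level in an embryo stage is compared with the paternal (F0)
sperm of the same group and classified into the seven-category scheme:
*total-hypo* (de-methylated, split into *free-hypo*, completely erased,
and *other-hypo*) and *total-hyper* (re-methylated, split into
*full-hyper*, completely methylated, and *other-hyper*), plus
*unchanged*. The verbal category definitions carry no canonical
numeric cutoffs; we use a minimum change of `delta_min = 0.1` (the same
granularity as the DMR thresholds), `free_max = 0.1` for "completely
erased" and `full_min = 0.9` for "completely methylated", all
configurable. Embryo stages are single scWGBS profiles, so region
levels are pooled counts with no replicate testing — this matches the
one-profile-per-stage-per-group design the package targets.

Heritable and un-heritable DMRs are contrasted per category with 2×2
Fisher exact tests against an equal-sized, seeded sample of
un-inherited F0 DMRs, optionally matched on deciles of the F0
$|\Delta\beta|$ (the external description says only "equal-sized";
matching removes an obvious confounder and can be toggled). The
contrast is run separately for de-methylated and re-methylated DMRs:
pooling directions cancels the signal at the reestablishment stage.

Cross-stage trajectories threshold the stress-minus-control difference
at each stage at ±0.1 into hypo/hyper/unchanged and tally the
ICM–PS–PGC pattern strings. Three states over three stages give exactly 27
combinations, which the frequency table enumerates exhaustively (a
count of 36 is sometimes quoted for this construction, but no
factorisation of three states over three stages yields 36, so the
package enumerates the 27 derivable patterns and notes the discrepancy
here rather than guessing a missing factor).

The escape analysis profiles region classes (imprinted genes,
transposable element families, VM-IAPs) that are highly methylated in
sperm (level > 0.8): a region *maintains* its state at a stage when its
level stays within 0.1 of sperm, is *erased* at ≤ 0.1, and is
*intermediate* otherwise (maintained takes precedence, so the three
fractions partition). VM-IAPs are first filtered on between-sample
variability — regions whose sperm level has standard deviation > 0.1
across all 18 sperm samples are metastable epialleles whose state is
not treatment-related, and they are removed before site-level
erasure/reestablishment proportions are computed. A site counts as
reestablished at PS when it is at least 0.1 above its ICM level and
reaches within 0.1 of its sperm level; among re-methylated sites the
fraction remaining below sperm is reported separately.

## sncRNA analysis

Counts of annotated sncRNA sequences (the package consumes
pre-annotated tables; multi-database read annotation happens upstream
and is out of scope) are normalised to reads per million. A unit
(subclass or unique sequence) is tested only if its six-sample count
sum exceeds 15 and RPM sum exceeds 1; the test is a two-sample t-test
on RPM at raw $p < 0.05$ with no multiplicity correction — the
screen's conventional form, with `adjust = "BH"` available.
The default is the pooled-variance Student test: at three replicates
per arm it holds the nominal 5% type-I rate on simulated
negative-binomial counts, where the Welch variant is measurably
conservative (~3%); `var_equal = FALSE` selects Welch.

Sequence matching to DMR sequences uses a 7 bp seed window: every
window of the sncRNA (direct) and of its reverse complement
(antisense) is located in the DMR sequence and extended maximally;
per (sequence, DMR, mode) the longest ungapped exact alignment is
recorded, which equals the longest common substring whenever that is
≥ 7 (verified against a dynamic-programming oracle in the tests).
Windows step by 1 nt and overlapping hits collapse to the single
longest alignment; ambiguous bases never match. The per-DMR *burden* is
the number of distinct differential sequences with at least one match,
compared between heritable and un-heritable DMRs by Mann–Whitney.
tsRNA target pairs require a perfect antisense 7-mer shared with the
mRNA sequence.

## The synthetic-data generator

The generator exists so that every stage can be exercised and
validated offline; its defaults are the study conditions the package
assumes:

* 18 sperm samples (2 groups × 3 generations × 3 replicates); per site,
  coverage is Poisson (mean 20×; embryo profiles 15×, reflecting the
  shallower single-cell libraries) and the methylated count is
  beta-binomial with replicate dispersion 0.03 — mid-range for WGBS
  biological replicates.
* Background site means are bimodal (75% mass near 1, 25% near 0),
  mimicking the sperm methylome's concentration at high methylation.
* Planted regions: 100 transgenerational, 400 intergenerational-only,
  1,500 F0-only and 200 null regions of 300 bp with 8 CpGs each;
  stress-group effects of $|\Delta\beta| = 0.3$ in the affected
  generations, attenuated ×0.8 per generation.
* Embryo trajectories: ICM retains 10% of the sperm level, PS
  reestablishes per site with probability 0.55 (yielding the bimodal
  mixed-level PS profile), PGC retains 5%; imprinted genes erase less
  at ICM and most thoroughly at PGC; a configurable fraction (3%) of
  TE/VM-IAP regions escapes ICM erasure entirely; heritable regions
  receive a group offset of 0.3 on the reestablished PS level along the
  planted direction.
* VM-IAPs: 105 regions of which 18/105 are metastable (per-sample level
  shifts, SD > 0.1) to exercise the variability filter.
* sncRNAs: negative-binomial counts (dispersion 0.02 — tight,
  high-count replicate behaviour; larger values make a 3× fold change
  undetectable at $n = 3$ and the planted-recovery checks
  meaningless), planted 3× fold changes for 60 up-regulated tsRNAs, 90
  down-regulated miRNAs and 20 down-regulated rsRNAs; half of the
  heritable DMR sequences embed 8–10 bp complements of five distinct
  differential sequences each (a single embedded fragment is
  statistically invisible against the high random 7-mer background
  between 20–35 nt sequences and 300 bp regions).

All randomness derives from one seed (embryos and sncRNAs use fixed
offsets of it), so identical configurations are bit-reproducible.

**What passing the synthetic checks shows — and what it does not.** The
generator matches the caller's model family (Poisson coverage,
beta-binomial replicates, independent sites outside planted regions).
Real WGBS data adds alignment artefacts, coverage biases, correlated
errors and non-CpG contamination that the generator deliberately omits;
the checks therefore validate the statistical machinery and its
calibration under its own assumptions, not performance on any
particular real dataset.

## Problem sizes and numerical choices

The validation suite runs a 100k-CpG null calibration, ten 1 Mb null
genomes for the false-region rate, one full 2×5 Mb recovery design
(2,200 planted regions), twenty seeded reprogramming-contrast runs,
exhaustive Fisher-vs-hypergeometric comparison over all 2×2 tables with
$n \le 40$, 200 random seed-matching oracle pairs and ~2,000-sequence
sncRNA calibrations — sizes chosen so the full suite completes in a few
minutes on one core while every check retains adequate statistical
resolution.

Degenerate inputs have defined behaviour throughout: zero-coverage
sites are errors at the level computation and absent records
everywhere else; zero-variance t-tests return $p = 1$ when means agree
and use a variance floor otherwise; Fisher tables with empty margins
are flagged degenerate with $p = 1$ and an undefined odds ratio;
Wilcoxon zero differences are excluded before ranking; empty inputs
return empty, correctly-typed tables.

## Known limitations

* The smoothed Wald test approximates a local-FDR thresholding scheme
  with BH; the internals of the reference implementation are not
  reproduced bit for bit.
* Single-profile embryo stages mean all stage-level inference is
  descriptive (thresholded levels), not replicated testing.
* The Wilcoxon inheritance route cannot reach stringent significance at
  $n \le 3$ pairs by construction; it is a sanity cross-check.
* Matching is ungapped and exact; wobble pairing and gapped alignments
  are out of scope.
* Paired designs, covariates and maternal-line inheritance are not
  modelled.
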