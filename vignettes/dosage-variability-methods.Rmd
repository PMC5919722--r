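---
title: "Methods: gene-dosage expression variability, the delta statistic, and the telegraph model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-dosage expression variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosevar)
```

## The problem

Deficiency (Df) fly lines each carry a heterozygous deletion removing a
contiguous block of roughly forty genes, leaving those genes with one
genomic dose instead of two. Profiling many such lines by RNA-Seq, in both
sexes and with biological replicates, yields thousands of one-dose
gene measurements and a much larger pool of two-dose measurements of the
same genes in other lines. `dosevar` asks whether reduced dose makes
expression *more variable* at the organism level, how that extra
variability relates to the strength of each gene's dosage response, and
whether chromatin-level machinery (the MOF acetyltransferase, acting in
the MSL complex on the male X and the NSL complex at autosomal
housekeeping genes) damps it.

## The delta statistic

With only two replicates per condition a per-gene noise estimate is
meaningless, so variability is measured per (gene, line) as

$$\delta = \frac{2\,|F_1 - F_2|}{F_1 + F_2} \in [0, 2),$$

where $F_1, F_2$ are the replicate FPKM values. $\delta$ is scale-free,
and for a pair it equals exactly twice the coefficient of variation under
the population (divisor-$n$) convention — which is why `cv()` defaults to
that convention; the identity is exact at machine precision, not
asymptotic. Because a single $\delta$ carries almost no information about
one gene, the package only ever compares *pools* of $\delta$ values
between gene groups (one-dose vs two-dose, dosage-response bins, sexes)
with two-sided Wilcoxon rank-sum tests (`compare_groups()`: exact
enumeration for small untied samples, normal approximation with tie
correction otherwise). For triplicate designs `delta_multi()` averages
$\delta$ over the three unordered pairs.

Genes enter a pool only if expressed in **every** replicate of the
group being summarised. The cutoff comes from intergenic background
signal: `derive_cutoff()` takes the 95th percentile (linear
interpolation) of the intergenic FPKM distribution. The phrase "median
of the top 95 percentile" that motivates this rule admits a second
reading — the median of the top-5% tail — which is exposed as
`method = "top_tail_median"`; the percentile reading is the default. For
real cohorts the published whole-fly threshold is available as
`fixed_cutoff()` (0.6829118 FPKM).

A complementary view of the one-dose effect is `median_null()`: the
observed median $\delta$ of all one-dose (gene, deleting-line)
measurements is compared against a null distribution built by re-assigning
each such gene to a random line where it is two-dose. The resampling
scheme is genuinely open — the original histogram could equally have been
built per line — so both are implemented (`scheme = "gene_resample"`,
the default, and `"per_line"`), and neither is asserted to be the
original. The empirical p-value uses the add-one rule
$(1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)$ so it can never be zero.

## Dose assignment and dosage response

`assign_dose()` intersects gene spans with deletion intervals (both
0-based half-open, the BED convention, kept uniform across the package):
fully contained genes are one-dose, disjoint genes two-dose. A gene
partially overlapping a deletion boundary is *excluded* in that line
(dose `NA`) — how boundary genes were originally handled is not
documented, and exclusion avoids mislabeling either way.

The dosage response of a one-dose gene is measured against the
no-regulation baseline of twofold reduction. With fold change
$FC$ = (Df line mean) / (pooled same-condition two-dose line means),

$$\text{response} = |\log_2 FC + 1|,$$

so exact halving scores 0 while full compensation ($FC = 1$) and twofold
anticompensation ($FC = 0.25$) both score 1. The printed form of this
definition elsewhere places the "+1" inside the logarithm, which cannot
reproduce its own stated baseline (halving would then score
$|\log_2 1.5| \ne 0$); the shifted reading above is therefore the
default, with the literal form available as `formula = "literal"` for
comparison. For binning (`response_bin`), rounding to the closest integer
is applied to $\log_2 FC$ before the shift, using round-half-to-even;
ties at .5 in log2 space are rare and the convention is stated rather
than consequential. Bins at or above 2 are pooled (`bin_vs_delta()`),
and adjacent bins are compared by rank-sum test. No single control line
is designated: the two-dose pool of the same sex and tissue is the
control, which matches the cohort design where every line is wild-type
for most of the genome.

## Occupancy-stratified CV

For chromatin analyses the 99 lines act as pseudo-replicates:
`gene_cv_table()` computes, per gene and condition, the CV of expression
across lines where the gene is two-dose, excluding the entire
deletion-bearing arm (2L by default) and requiring at least three usable
lines. Whether the original computation averaged replicates within a line
first is unknown; the default averages (`per_line = "mean"`) and the
all-samples variant is one argument away. Occupancy is binarised as
any-overlap (>= 1 bp, half-open) between the gene span and a called peak;
peak calling itself is upstream and out of scope. Housekeeping status is
tau strictly below the 5th percentile of the observed tau distribution;
genes lacking tau, EBox or NSL annotations drop out of the corresponding
stratification only. `stratified_compare()` then tests flagged vs
unflagged CV within each stratum (X vs autosome, housekeeping or not,
EBox or not, NSL-activated or not).

## The telegraph model and population averaging

The stochastic simulation asks whether gene-intrinsic transcriptional
noise could explain organism-level variability. Each gene copy switches
between OFF and ON at rates $k_{on}, k_{off}$, transcribes at $s_A$ while
ON, and mRNA decays at $\delta_M$ per molecule. `simulate_cell()` is an
exact Gillespie simulation (compiled kernel, driven by R's RNG so
`set.seed()` governs everything) starting from all copies OFF and zero
mRNA; two-dose genes are two independent reaction channels in one
simulation, which is equivalent to two separate runs and faster.

The reference regime (`telegraph_presets()`) is
$k_{on} = k_{off} = 0.02\,/s$ (switching half-time
$\ln 2 / 0.02 \approx 35$ s), $s_A = 0.01\,/s$ (0.02 for the compensated
one-dose gene), $\delta_M = 0.008\,/s$. The degradation rate is quoted
elsewhere alongside a 14-minute half-life, which is mutually inconsistent
($\ln 2/0.008 \approx 87$ s); the rate is taken as authoritative and a
`half_time_14min` preset exposes the other reading. Two closed forms
serve as independent oracles for the simulation:

- stationary mean $= n_{copies} \cdot \frac{k_{on}}{k_{on}+k_{off}}
  \cdot \frac{s_A}{\delta_M}$ (0.625 for the uncompensated one-dose
  regime, 1.25 for two-dose);
- Fano factor $= 1 + \frac{s_A k_{off}}{(k_{on}+k_{off})
  (k_{on}+k_{off}+\delta_M)} \approx 1.104$, copy-number independent.

A "population measurement" is the mean over $N$ independent cells at one
observation time after a burn-in of $5/\delta_M$ (the choice of a single
observation time is the package's own protocol; per-cell time averaging
over the post-burn-in window is available via `observe = "time_average"`
and is the lower-variance estimator used where only the stationary mean
matters). `population_delta()` applies $\delta$ to two independent
population measurements; by the central limit theorem its mean falls off
as $N^{-1/2}$, which `delta_vs_popsize()` traces and
`delta_curve_slope()` verifies (fitted log-log slope $\approx -0.5$
across sizes spanning two or more decades). For a single cell at these
rates the mRNA count is zero roughly a third of the time, so the
two-replicate $\delta$ is occasionally undefined (both means zero); such
draws are redrawn with fresh derived sub-seeds (bounded at 100 attempts)
rather than propagating an error out of a single unlucky pair.
Reproducibility uses counter-based seeding: every (size, repeat,
replicate) derives its own sub-seed from the base seed, so curves are
reproducible and trivially parallelisable.

## The synthetic cohort generator

Real cohort data live behind external accessions, so the package ships a
generator whose defaults mirror the study design: 99 deficiency lines on
2L deleting 40 contiguous genes each, two sexes, two replicates,
log-normal FPKM. On the log2 scale,

$$\log_2 F_{g\ell r} = \log_2 B_g + d_{g\ell} + \varepsilon_{line}
  + \varepsilon_{rep},$$

with dose term $d = 0$ (two-dose) or $-1 + \rho_g$ (one-dose), where
$\rho_g \sim N(0, \sigma_\rho)$ is the planted dosage response measured
against the halving baseline — this aligns the planted magnitude with
what `response_score()` computes, since $\log_2 FC + 1 = \rho_g$ in
expectation. Both noise terms are multiplied by a dispersion factor
$\kappa$:

$$\kappa = \underbrace{(1 + \alpha_0 + \alpha_1 |\rho_g|)}_{\text{if
one-dose}} \cdot \underbrace{m}_{\text{if occupancy-flagged}} \cdot
\underbrace{\gamma_F}_{\text{if female}}.$$

$\kappa$ scales the *per-replicate* biological noise, not only a shared
line effect. This is deliberate: $\delta$ is computed between replicates
within one line, and the occupancy analysis computes CV across lines
where genes are *two-dose* — so a one-dose inflation confined to a
line-level effect would be invisible to $\delta$, and an occupancy shrink
confined to one-dose measurements would be invisible to the CV table.
Placing $\kappa$ on both noise components (with the occupancy and sex
factors applying at all doses, and the one-dose inflation only when dose
is reduced) is the simplest generative model in which all four planted
orderings are recoverable by the statistics that are supposed to recover
them. Effects are multiplicative on the log scale because $\delta$ and CV
are scale-free: only log-scale dispersions matter, and mean shifts cancel
exactly.

Defaults are chosen once as realistic magnitudes: baseline
$\log_2 \text{FPKM} \sim N(3, 1.5)$; replicate noise sd 0.25 and line
effect sd 0.2 (log2), giving two-dose median $\delta \approx 0.15$–0.2,
the scale seen in replicated fly RNA-Seq; $\alpha_0 = 0.5$ (a 50%
dispersion inflation at zero response), $\alpha_1 = 0.6$,
$\sigma_\rho = 0.8$ (wide compensation heterogeneity, so the $\ge 2$
response bin is populated with a few hundred measurements, as in real
cohorts); occupancy fraction 0.3 with shrink $m = 0.6$; female multiplier
1.3; fully compensated male X (dose term 0, no inflation). Spike-ins
carry only technical noise (sd 0.05, far below biological noise) and are
flagged in the annotation rather than inferred from id patterns, since
naming conventions are not guaranteed. Intergenic background is
log-normal with meanlog $\log 0.05$ and sdlog 1.55, making the true 95th
percentile analytic ($\approx 0.64$ FPKM, close to the published
threshold) so the cutoff code can be checked in closed form.

What the generator does **not** emulate: count-level sampling noise and
its mean-variance relationship, batch structure, correlated
co-regulation, real peak geometry, annotation errors, or genes split
across Df boundaries (deletions are aligned to gene blocks, so the
partial-overlap exclusion rule is exercised by unit fixtures instead).
Passing recovery tests therefore shows the statistics detect the planted
structure at realistic effect sizes — not that real data contain those
effects.

## Problem sizes and numerical choices

Unit tests run on compact cohorts (a few hundred genes, 12 lines);
recovery and calibration checks run the full default cohort (2020 genes,
99 lines, 396 samples) across 20 seeds, and simulation checks use
10^4–2×10^4 cells with population sizes spanning 10–10^4 — sizes at
which every Monte-Carlo comparison has comfortable margin against its
3-standard-error band. Percentiles use linear interpolation (R type 7)
throughout. Degenerate inputs error early with explicit messages: empty
intergenic vectors, non-positive fold changes, groups with an empty side,
genes never measured two-dose (dropped with a warning and a count).
Results written by `run_cohort_analysis()` carry a commented header
(package version, seed, cutoff) and a JSON manifest so any table can be
regenerated from its config alone.

## Limitations

- $\delta$ is a group-level instrument by construction; nothing in the
  API produces a per-gene noise estimate, and none should be read off a
  single DeltaRecord.
- The rank-sum tests treat measurements as exchangeable within pools;
  records sharing a gene across lines are weakly dependent, which the
  original design accepts and this package inherits.
- The telegraph simulation covers intrinsic noise only. Extrinsic noise
  (cell-to-cell parameter variation) is argued about by elimination, not
  simulated.
- FPKM computation, read alignment, and peak calling are upstream: the
  package starts from tables and intervals.
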