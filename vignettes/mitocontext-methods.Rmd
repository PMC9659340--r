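---
title: "Methods: haplogroup-context analysis of mtDNA variant combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplogroup-context analysis of mtDNA variant combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocontext)
```

## The problem

Human mtDNA evolves along strictly maternal lineages, so the variants that
define a haplogroup are inherited as one fully linked block. A functional
variant is therefore always tested by selection *in the context of* the
background it arose on. Clinical practice, however, usually evaluates
pathogenicity one variant at a time, by its global allele frequency. A variant
that is common — and benign — on its native background can be deleterious when
it recurs by homoplasy on a background where it is essentially never observed.
`mitocontext` provides the statistics for detecting exactly this situation:
haplogroup-conditional allele frequencies, a normalized pairwise cooccurrence
statistic with an exact independence null, and a pedigree transmission-skew
test for a protective nuclear modifier. It also implements the quantitative
computations of the cell assays used to characterise such variant
combinations (NADH FLIM fitting, respirometry state extraction,
flow-cytometry ratio metrics), so a full analysis can be rehearsed end to end
on synthetic data.

## Variant and catalog model

Variants are binary presence/absence single-nucleotide substitutions in rCRS
coordinates (`m.<pos><ref>><alt>`, positions 1..16569). Heteroplasmy
fractions and indels are deliberately out of scope: the population statistics
operate on catalog-level presence calls, and indel nomenclature is rejected
with a distinct error rather than silently coerced. mtDNA is treated as
haploid, so any non-reference VCF genotype counts as presence.

A *catalog* is one record per sequenced individual: a sample id, a haplogroup
label, and a variant set. A *haplogroup tree* attaches to each named node the
variants gained on the edge leading to it; the root-to-node union is the set
expected in every member. The tree validator enforces a single root,
acyclicity and — reflecting complete linkage — that no variant is gained
twice on one root path.

## Haplogroup assignment

The assigner scores each node as the mean of two fractions: the share of the
node's path variants present in the sample (path coverage) and the share of
the sample's variants explained by the path. A degenerate fraction (empty
path or empty sample) is defined as 1, so the empty record maps to the root.
Ties break toward greater depth, then lexicographic name. This
Kulczynski-style scorer is far simpler than production haplogroup callers
(no phylotree weights, no quality terms), but it has the property the
pipeline needs: exact recovery on noise-free defining-variant sets, which the
test suite verifies across randomly generated trees. A single private variant
perturbs each score by at most `1/(2 * |sample variants|)`, so assignments
with a larger margin are stable under private mutations.

## Conditional allele frequencies

`conditional_allele_frequency()` counts carriers within one haplogroup
stratum. Frequencies are reported as exact fractions plus a display
percentage rounded half-up to two decimals (3/348 = 0.8621% displays as
0.86%); half-up rather than banker's rounding is used because it is the
convention of the frequency tables this mirrors. Strata are taken from the
catalog labels as given; whether a label subsumes sublineages is the
catalog's concern, not the package's.

## Normalized cooccurrence and the independence null

For variants $i, j$ with carrier counts $n_i, n_j$, joint count $n_{ij}$ and
catalog size $N$, the normalized cooccurrence is

$$ r_{ij} = \frac{n_{ij}/N}{(n_i/N)(n_j/N)}, $$

which is 1 under independence, $1/f$ under perfect linkage at frequency $f$,
and 0 for mutually exclusive variants. Pairs with a zero margin are emitted
as flagged-undefined rows, never dropped.

The under-cooccurrence test conditions on both margins: under the null that
variant $j$'s carriers are an unordered random sample of $n_j$ of the $N$
records, the overlap is central hypergeometric, and the one-sided p-value is
$P(X \le n_{ij})$. The test is exact, and the suite checks it against
exhaustive enumeration of all count configurations up to $N = 12$ and against
a permutation oracle. Because the statistic is discrete the exact tail is
conservative; for calibration diagnostics the package also offers mid-p and
randomized variants (the randomized tail is exactly uniform under the null),
while inference defaults to the conservative exact form. Multiplicity across
a matrix run is handled by Benjamini–Hochberg over all defined off-diagonal
pairs, with a default significance level of 0.05.

`flag_out_of_context()` composes these pieces: every pair of variants within
one individual is screened against the population, and pairs with ratio below
1 and BH-adjusted q below 0.05 are reported — the "common variant on the
wrong background" signature. Ratios are computed on the full catalog by
default, matching a population-wide database analysis; a stratified mode
(restricting to chosen haplogroup labels) is available for users worried
about population structure, but is off by default.

## Transmission skew and noncarrier lethality

If a father is heterozygous for a protective nuclear allele, Mendelian
segregation predicts half the conceptions inherit it. The skew test is the
one-sided binomial tail $P(X \ge k)$ for $k$ carriers among $n$ survivors —
one-sided because the hypothesis is directional.

The likelihood-ratio formalization compares two models of the conception
outcomes. Both share Mendelian segregation and a genotype-independent
baseline in-utero loss probability $d$; the alternative adds
noncarrier-specific lethality with penetrance $\pi$, so a conception is a
surviving carrier with probability $(1-d)/2$, a surviving noncarrier with
probability $(1-d)(1-\pi)/2$, and a miscarriage otherwise. Miscarriage
genotypes are marginalized, never imputed. The nuisance $d$ is profiled out
by maximum likelihood in each model separately; this makes the models
coincide exactly at $\pi = 0$ (log-LR 0) without having to invent a fixed
survival rate, which the data cannot identify. At $\pi = 1$ a single
surviving noncarrier makes the alternative impossible (log-LR $-\infty$),
which is the correct behaviour for a fully penetrant lethal model.

## NADH FLIM fitting

Each pixel of a time-correlated single-photon-counting acquisition is a
photon histogram over 256 channels spanning one 12.5-ns pulse period. The
model is a biexponential with both lifetimes fixed — 400 ps for free NADH,
2500 ps for protein-bound NADH — plus an optional flat background:

$$ m_t = A\left(a_1 e^{-t/\tau_{free}} + (1-a_1)e^{-t/\tau_{bound}}\right) + bg. $$

Only the amplitude structure is free, and the amplitude-weighted mean
lifetime $\tau_m = a_1\tau_{free} + (1-a_1)\tau_{bound}$ reports the
NAD⁺/NADH redox state. Throughout the package (generator and fitter alike)
$a_1$ is the amplitude fraction of the *short* (free) component, so
$a_1 = 1$ gives 400 ps.

Numerical choices:

* **Weights.** The objective is weighted least squares with
  $w_t = 1/\max(y_t, 1)$ — the Poisson-variance weighting with a floor that
  avoids zero-count singularities. The floor makes the reduced
  $\chi^2$ of a well-specified fit land slightly above 1 on average, safely
  inside the 1.2 quality bound used for acceptance.
* **Profile strategy.** For fixed $a_1$ (and shift) the model is linear in
  $A$ and $bg$, so those are solved in closed form and $a_1$ is found by 1-D
  golden-section search on $[0,1]$, with the interval ends checked
  explicitly. This is robust (no starting values, no divergence) and fast
  enough for per-pixel use. Only when the channel shift is also fitted does
  the package fall back to L-BFGS-B over $(a_1, shift)$.
* **Time origin.** The decay is fitted from the histogram peak channel
  onward, at channel centers; channels before the peak are excluded. An
  ideal-pulse model is used — no instrument-response deconvolution — which
  matches the fixed-lifetime amplitude-fitting regime; the channel shift
  parameter exists to absorb small timing offsets and is frozen at 0 by
  default, mirroring the practice of fixing the shift at a pixel of clear
  signal.
* **Masking.** Curves whose peak falls below the (background-adapted) peak
  threshold are masked, not fitted. Image fitting sums each pixel with its
  $(2b+1)^2$ square neighbourhood before fitting (binning $b = 0$ is exact
  per-pixel fitting) and reports the mean reduced $\chi^2$ against the 1.2
  bound.

## Respirometry state extraction

Oxygen-flux traces are piecewise plateaus punctuated by titrations. Two
protocols are modelled: intact cells (Routine → oligomycin/Leak → stepwise
FCCP/ETS → antimycin/background) and permeabilized cells (Routine →
digitonin+substrates/L\_S → ADP/CI → succinate/Ox → oligomycin/L\_Olg →
FCCP/ETS → rotenone/CII → antimycin/background). Each state is the *median*
of the final 60 s of its segment — the plateau-averaging rule is not
standardised, and a terminal-window median is robust to the transient spike
right after a titration. ETS is the maximum across FCCP steps, as the
stepwise titration deliberately brackets the optimum. The post-antimycin
background is subtracted from every state (itself becoming exactly 0), and a
state-table flag refuses double subtraction. Because the exact definition of
"respiratory control ratios" varies, the package emits three ETS-normalized
candidates — Routine/ETS, Leak/ETS and (Routine−Leak)/ETS — and labels them
as an interpretation rather than presenting any one as canonical.

## Flow-cytometry and normalization metrics

All fluorescence metrics first subtract the unstained-control mean from each
channel; a negative corrected intensity is floored at 0 and flagged (a
corrected denominator of 0 is an error). On top of that sit simple ratios:
PE/FITC for JC-1 membrane potential, BV650/PerCP for Fura Red cytosolic
calcium, the ionomycin/untreated calcein ratio normalized to control for mPTP
opening, and ROS flux per O₂ flux normalized to control. Every
normalized-to-control metric returns exactly 1 when the sample equals the
control, which the suite asserts across random fixtures.

## What the generators emulate — and what they do not

The catalog generator reproduces the statistical structure the analyses rely
on: complete linkage of haplogroup-defining variants (each record carries its
full root-path union), Poisson-distributed private variants at unused
positions (transitions only — composition does not affect presence/absence
statistics), independent recurrent homoplasies at a configurable per-sequence
rate, and exact-count injections for planting out-of-context variants. It
does not model realistic mutational spectra, branch lengths, back-mutation,
heteroplasmy or multi-generation selection; passing tests therefore
demonstrate the statistics' correctness under their own null, not robustness
to population structure in real databases. The independence model doubles as
the null for calibration: with homoplasies only, normalized cooccurrence
averages 1 and the randomized p-values are uniform.

The decay generator draws independent Poisson counts around the biexponential
model at channel centers plus a flat background; it shares the model with the
fitter, so recovery tests validate the estimator, not the physical realism of
an ideal pulse. The trace generator produces Gaussian-noised plateaus with
optional linear drift and records the titration markers; all generators are
deterministic in (config, seed).

Default study conditions mirror the motivating analysis: a 348-record H7
stratum with 3 injected carriers of m.13708G>A (conditional frequency 0.86%)
against a 348-record J stratum; a 15-conception pedigree with 8 surviving
carriers and 7 miscarriages; 256-channel decays over 12.5 ns at 400/2500 ps.

## Problem sizes and tolerances

The test and acceptance runs use: null-calibration catalogs of $N = 10{,}000$
records (20 variants for the mean-ratio check; 2,000 variants paired
disjointly for 1,000 independent p-values in the uniformity check);
exhaustive hypergeometric enumeration for all $N \le 12$; permutation oracles
of $10^5$ draws on 50 random instances; 100 seeded single-pixel decays at
$10^5$ photons for FLIM recovery (a1 within ±0.02, mean reduced
$\chi^2 < 1.2$); 500 replicate noisy traces for respirometry unbiasedness.
These sizes give Monte-Carlo error comfortably below the asserted tolerances
while keeping a full run in the low minutes.

## Known limitations

* The cooccurrence ratio is computed on the full catalog; real population
  databases are strongly structured, and the hypergeometric null does not
  model that structure. The stratified mode mitigates but does not remove
  this; depressed cross-haplogroup ratios between *defining* variants are
  expected by construction and are informative only for variants observed on
  multiple backgrounds.
* The haplogroup assigner is intentionally minimal and should not replace a
  production caller on noisy real-world sequences.
* The lethality likelihood ratio conditions on the observed family and makes
  no claim about ascertainment (families are typically noticed *because* of
  their survivors).
* FLIM fitting assumes the fixed two-lifetime model; it does not fit
  lifetimes, more components, or an instrument response function, and its
  $\chi^2$ is comparable across pixels only under the shared weighting rule.
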