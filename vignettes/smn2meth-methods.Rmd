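---
title: "Models and methods behind smn2meth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smn2meth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smn2meth)
```

`smn2meth` analyses targeted CpG methylation across the duplicated *SMN2*
locus in SMA cohorts. This vignette documents the statistical model, the
filtering rules and their exact boundaries, the synthetic-data generator,
and the design decisions taken where more than one defensible choice
existed.

## From calls to a methylation matrix

The unit of raw data is a strand-resolved call record: modified (`n_mod`),
canonical (`n_can`) and ambiguous/filtered (`n_filt`) read counts at one
cytosine. Methylation percentage is

$$100 \cdot \frac{N_{mod}}{N_{mod}+N_{can}},$$

undefined (missing) at zero unambiguous depth. Filtered calls never enter
the formula, neither in the numerator nor the denominator: they represent
reads the caller abstained on, not evidence either way. The same logic
applies to the depth filter — "depth" throughout means $N_{mod}+N_{can}$,
so a cell can be masked even if many reads were seen but few were called
confidently.

A CpG dinucleotide carries a cytosine on each strand; calls at the
forward-strand C (position $c$) and reverse-strand C ($c+1$) are summed
component-wise into one site keyed at $c$. Bismark coverage files do not
encode strand, so those records are assigned a role purely by position
within the reference CpG map. Two records claiming the same strand of the
same site in one sample indicate an input-preparation fault and raise an
error rather than being silently summed. Calls matching no CpG in the map
are reported as off-target and excluded.

Filters compose in a fixed order — on-target restriction, depth mask,
SNV removal — and are monotone: no filter ever adds a site or turns a
missing cell into a value. Boundaries are strict where stated: a cell at
exactly the minimum depth (default 100×) is **kept**; a site with
cross-sample standard deviation exactly 5 percentage points is **kept**
(removal is SD < 5); a correlation of exactly 0.9 does **not** collapse
(collapse is R > 0.9); significance is adjusted p **strictly below** 0.01.

### SNV masking

At a CpG whose C or G is a known variant position, bisulfite or
modified-base signal reflects genotype, not methylation: a destroyed CpG
either loses the modification or loses the caller's ability to see it.
`mask_snv_cpgs()` therefore removes a site exactly when an SNV is recorded
at $c$ or $c+1$, and reports what it removed with the triggering variant.
An SNV at $c-1$ (the base before the C) does not touch the site. The
quantitative consequence of *not* masking is the dilution law tested in
the acceptance suite: if $k$ of $K$ copies carry a destroyed CpG whose
reads are still read and called canonical, pooled apparent methylation
tends to $m\,(K-k)/K$ as depth grows.

### Haplotypes and environments

Patients carry 2–5 *SMN2* copies; per-haplotype call files become columns
`sample.hapK` with identical filter semantics. A haplotype's genomic
environment (SMN1-like vs SMN2-like conversion history) is classified from
marker SNVs by a **unanimity rule**: `SMN1-env` only if every genotyped
marker carries the SMN1-environment allele, likewise `SMN2-env`, and
`mixed/unknown` otherwise (including zero genotyped markers). No published
rule exists for discordant haplotypes; unanimity is the conservative
choice and simply excludes them from the two-group environment contrast,
which is how such contrasts are analysed in practice. The marker list
itself is an input; the package ships only a synthetic stand-in in its
simulator.

## Site reduction

Before testing, sites with SD < 5 percentage points across samples are
removed (they cannot carry a detectable signal at cohort scale and inflate
the multiple-testing burden), and highly correlated sites (Spearman
R > 0.9, pairwise-complete observations, average ranks for ties) are
collapsed by averaging. "Treated as one site" does not by itself define a
grouping when correlation is not transitive; `collapse_correlated()` uses
**connected components** of the pairwise graph — the unique parameter-free
closure of the pairwise rule. Greedy pairwise merging would give
order-dependent groupings; components do not. Group values are unweighted
means over non-missing members, so a sample missing one member still gets
a collapsed value; collapsing is not restricted to within-amplicon pairs.
The bookkeeping identity (outputs + Σ(members − 1) = inputs) and
idempotence are asserted in the test suite.

## Per-site differential methylation

For each site, ordinary least squares with intercept:

$$\text{meth\%} \sim \text{independent} + \text{covariates},$$

with the standard covariate set age at sampling, sex, library size per
*SMN* copy, and GQN (DNA quality). Age is dropped from the covariates
automatically when it is the variable under test. Encodings are fixed and
documented: sex male = 0 / female = 1; tissue blood = 0 / fibroblast = 1;
SMA type 1–4 → 0–3 with presymptomatic patients excluded from the type
contrast (the ordinal mapping assigns them no rank); copy numbers enter as
numeric. Library size per *SMN* copy enters untransformed; a user can pass
any transformed column instead.

Missingness is handled by per-site listwise deletion — call rates in
targeted data are near-complete, and imputation would manufacture
precision. The coefficient of the independent variable is tested two-sided
against $t_{n-p}$; p-values are adjusted across all tested sites of a scan
with Benjamini–Hochberg (the standard FDR method, `p.adjust(method="BH")`
on the non-missing p-values, so missing fits do not count toward $m$).
Degenerate fits are flagged, not guessed at: rank-deficient designs and
zero residual df give missing results; a zero-variance response gives
estimate 0 with a missing p-value.

Internally a scan groups sites by missingness pattern and shares one QR
decomposition per pattern; this is an exact reformulation, verified
against single-site fits and a normal-equations oracle at $10^{-8}$.

### Severity dichotomisation and treatment response

The long-read severity contrast splits patients on SMA type *with*
subtype, on the scale 1a < 1b < 1c < 2a < 2b < 3a < 3b < 4 (lower = more
severe): with three *SMN2* copies, "type 2b or milder" vs "type 2a or more
severe"; with four copies, the split moves to 3b vs 3a. Other copy numbers
get no label, and a patient sitting exactly at the cut without a recorded
subtype stays unclassified. Treatment response groups change in HFMSE
score at ±3 points, inclusive: ≤ −3 decrease, −3 < d < 3 stabilization,
≥ 3 increase.

## Power analysis

`power_f2()` implements the general-linear-model power function: the F
statistic on $(u, v)$ df exceeds its central critical value at level
$\alpha$ with probability taken under the noncentral F with
$\lambda = f^2 (u+v+1)$. `required_sample_size()` solves this for the
continuous $v^\*$ at the target power and converts to a sample size.

Two df-to-n conventions exist and differ by $u$. The exact OLS accounting
is $v = n - u - 1$, giving $n = \lceil u + v^\* + 1\rceil$. A widely used
applied convention — the one under which the familiar medium-effect answer
of 115 patients ($f^2=0.15$, $u=4$, $\alpha=0.01$, power 0.8) arises —
takes the solved $v^\*$ as $n - 1$, i.e. does not add the slope df back
when converting to a sample size. The package defaults to the latter so
its headline numbers match the applied literature for this design, and
exposes the exact accounting (`convention = "u_plus_v_plus_1"`, 119 for
the same query) for users who want the conservative figure. Within either
convention the returned $n$ is minimal: $n-1$ fails the power condition.

## Exploration

PCA treats samples as observations and sites as variables, centred and by
default unit-scaled (scaling stops high-variance sites from dominating
PC1; both behaviours are exposed because the choice genuinely changes the
leading components). Sites with missing values are dropped and reported by
default, or mean-imputed on request. Component signs are fixed by making
each component's largest-magnitude loading positive, so score tables are
reproducible across platforms. Clustering is agglomerative ward.D2 on
Euclidean distances (distances not pre-squared; the criterion squares
internally), checked against a brute-force Lance–Williams implementation
on small instances.

## The synthetic cohort generator

Because the patient data this kind of analysis runs on are access
restricted, the generator is a first-class module: every pipeline stage is
exercised on cohorts with known ground truth.

Defaults are fixed once at realistic study conditions: 365 patients with
≈ 6/365 carrying a severity-modifying genotype (*SMN1* copy or c.859G>C),
*SMN2* copy-number marginal (15, 215, 122, 7)/359 over 2–5 copies with
SMA-type distributions conditional on copy number; balanced sex; uniform
sampling ages over 0–60 y (an age-by-copy-number confound can be planted
via per-copy-number age ranges); amplicon depths log-normal with median
3000× (long-read platform: 30×); bisulfite non-conversion/false-modified
rate ε = 0.005 and missed-modification rate δ = 0.01, entering the
observed call probability as $p(1-\delta) + (1-p)\varepsilon$; 2% missing
cells; per-patient, per-site biological noise of SD 0.3 on the logit
scale.

The generative model is **logit-linear**: baselines and effects live on
the logit scale so every cell is a valid probability, while the analysis
model is deliberately the field's linear model on raw percentages. Planted
slopes are specified in percentage points per unit and converted to logit
slopes at the affected site's baseline; effect scenarios place planted
sites at 50% baseline, where the logistic curve is flattest, so the
percentage-scale slope stays near-linear over the simulated range (the
residual curvature over 0–60 y contributes ≈ 2% attenuation, well inside
the 10% recovery tolerance the tests assert). CpG-destroying artifacts
deterministically destroy `round(f·K)` of a patient's K copies and come in
both plausible caller behaviours: destroyed copies read but always called
canonical (diluting pooled methylation by (K−k)/K) or dropped entirely
(halving depth, leaving the percentage unbiased).

What the generator does **not** emulate: read-level sequence context and
instrument-specific error profiles, spatial correlation of methylation
along the locus beyond what planted effects induce, phasing errors
(haplotype assignments are exact), cell-type composition, and batch
structure. Passing recovery tests therefore demonstrates correctness of
the estimation machinery under the stated model, not robustness to every
artefact of real data.

## Problem sizes and numerical tolerances

The test suite runs the type-I-error study at 100 seeded null cohorts of
200 samples × 500 sites (asserting that at most 5% of replicates produce
any adjusted-p < 0.01 discovery) and parameter recovery at 300 samples,
depth 2000×, 21 planted age-effect sites among 221 (≥ 95% sensitivity,
≤ 1% null discoveries, mean slope bias < 10%) — sizes chosen to give the
binomial/OLS asymptotics room while keeping the default suite under a
minute. Oracle agreements are asserted at 10⁻⁸ (OLS coefficients/SEs),
10⁻¹² (BH adjustment, Spearman, percentage arithmetic) and 10⁻⁸ (Ward
merge heights). Matrix TSVs print doubles with `%.17g`, so write/read
round-trips are bit-exact.

## Known limitations

* The linear model on percentages can predict outside [0, 100] and
  assumes homoscedastic residuals; at very high depths the binomial
  component is negligible, but at long-read depths (~30×) counting noise
  dominates and a beta-binomial model would be more efficient. The
  package implements the field-standard OLS deliberately.
* Connected-component collapsing can, in principle, chain weakly related
  sites through strong intermediates; the collapse map makes every
  grouping auditable.
* Environment classification trusts the supplied marker list; with no
  genotyped markers a haplotype is unclassifiable rather than guessed.
* The per-haplotype depth model splits coverage evenly across copies;
  real phasing yields uneven and occasionally ambiguous assignments.
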