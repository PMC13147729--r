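---
title: "Methods: age-related methylation analysis in sperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-related methylation analysis in sperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermage)
```

## The analysis model

The package implements an epigenome-wide association analysis of sperm DNA
methylation on age, for Illumina 450K-style arrays. The measurement is the
beta-value $\beta \in (0,1)$, the proportion of cells methylated at a CpG
site. Because beta-values are heteroscedastic near the boundaries,
regression is run on the M-value (log2-odds) scale,

$$M = \log_2\!\frac{\beta}{1-\beta}, \qquad
  \beta = \frac{2^M}{1+2^M}.$$

The log base is 2 throughout, chosen for consistency with the
back-transformation below, which is defined with powers of 2. Beta-values
are clipped to $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$
before the transform so M is finite everywhere; the guard is far below any
biologically meaningful methylation difference.

For each probe the model is ordinary least squares

$$M_{ij} = \alpha_i + b_i\,\mathrm{age}_j + c_i\,\mathrm{BMI}_j +
  d_i\,\mathrm{patient}_j + e_{ij},$$

with age in years (so $b_i$ is an M-value change per year; multiply by 10
for a per-decade reading), BMI continuous in kg/m², and patient status
coded 0/1. All probes share one design matrix, so the fit is a single QR
decomposition applied across the matrix.

### Empirical-Bayes variance moderation

With few subjects per probe, per-probe variance estimates are noisy. The
package moderates them under the standard hierarchical model in which the
true residual variances follow a scaled inverse chi-squared prior with
degrees of freedom $d_0$ and scale $s_0^2$. The prior is estimated by the
method of moments on the log residual variances: writing
$e_i = \log s_i^2 - \psi(d_i/2) + \log(d_i/2)$, the excess of
$\mathrm{var}(e)$ over $\psi'(d_i/2)$ identifies $d_0$ through a trigamma
inversion (solved by Newton iteration), and the mean of $e$ identifies
$s_0^2$. The posterior variance is the convex combination

$$\tilde{s}_i^2 = \frac{d_0 s_0^2 + d_i s_i^2}{d_0 + d_i},$$

and the moderated t-statistic $b_i / (\tilde{s}_i\, u)$ (with $u$ the
unscaled coefficient standard deviation) is referred to a t distribution
with $d_i + d_0$ degrees of freedom. When the observed spread of log
variances is no larger than its sampling noise, $d_0 = \infty$ and every
posterior variance equals $s_0^2$; forcing $d_0 = 0$ recovers the ordinary
t exactly, and both limits are unit-tested. Exact-zero variances are
floored at $10^{-12}$ before taking logs. The plain moderated-t variant is
implemented (no trend on intercept, no robust weighting); the test suite
cross-checks the estimates against an independent empirical-Bayes
implementation.

Multiple testing uses the Benjamini–Hochberg step-up procedure, applied
once, jointly across all probes that survive filtering. A probe is a
differentially methylated CpG (DMC) when its adjusted p-value is below
0.05.

### Subgroups and effect back-transformation

Probes are classified by their mean beta across subjects: unmethylated
(UM) below 0.20, hemi-methylated (HM) from 0.20 to 0.80 with both
boundaries inclusive, fully methylated (FM) above 0.80.

M-scale effects are translated back to the beta scale with the intercept
method,

$$\Delta\beta = \frac{2^{M_0+\Delta M}}{1+2^{M_0+\Delta M}} -
  \frac{2^{M_0}}{1+2^{M_0}},$$

where the baseline $M_0$ is taken as the probe's observed mean M across
subjects. The raw regression intercept would extrapolate to age zero with
uncentred covariates, which is not a meaningful baseline for a cohort aged
18–35, so the mean-M choice is the default (the function accepts any
baseline). $\Delta\beta$ always carries the sign of $\Delta M$, a
monotonicity property checked on $10^5$ random pairs.

### Probe filters

Three filters are available, applied with a fixed precedence so the filter
report is a partition: detection quality (a probe fails when its detection
p-value exceeds 0.01 — strict inequality — in at least one subject), then
SNP-flagged probes, then cross-reactive probes. Filtering is idempotent
and never permutes subject order. Normalization is deliberately out of
scope: the pipeline consumes beta-values that are already normalized, and
the loader is a natural hook for any external normalization step.

## Imprinted genes and imprint control regions

DMCs are mapped to imprinted genes by symbol, after uppercasing and
whitespace-stripping both sides; a probe annotated to several
semicolon-separated genes can match each of them. No alias resolution is
attempted — aliases belong in the curated input lists.

Imprint control regions (ICRs) arrive as 6-column BED (0-based, half-open)
with the name field `gene|origin`. A probe position $p$ hits an interval
$[s,e)$ iff $s \le p < e$, so a probe exactly at the `end` coordinate does
not hit; boundary cases are unit-tested, and the interval engine
(GenomicRanges) is verified against a brute-force all-pairs scan. No
flanking window is added by default, since no particular distance is
canonical; `flank` widens every interval symmetrically when a window is
wanted. A DMC inside two overlapping ICRs counts once as a DMC but
contributes two DMC–ICR pairings; a gene linked to ICRs of more than one
parental origin appears once per origin with a `multi_origin` flag.

## The score of interest

Gene-level biomarker ranking sums eight binary indicators: ICR-linked
(`icr`), co-listed by at least three external studies (`co`), at least two
significant DMCs (`multi_cpg`), membership in the top-90 set (`top90`),
at least one DMC with $|\Delta M| > 0.1$ per year (`ma`, strict), opposite
direction (`op`: methylation increasing at a UM site or decreasing at an
FM site), at least one island DMC (`is_island`) and at least one promoter
DMC (`pr`). All eight columns enter the sum — the packaged worked example
only reproduces its published scores with all eight. Two readings were
genuinely open and are resolved as follows: `co` counts membership in
external lists only (a gene's own discovery does not count toward it), and
`multi_cpg` counts significant DMCs, not all probes annotated to the gene.
The "top 90" is the union of per-subgroup top-30 lists (lowest adjusted p,
ties broken by raw p then probe id), even where a single global ranking
would differ.

Selection keeps disease-associated genes that are ICR-linked, plus
disease-associated genes without an ICR link whose score reaches 3, then
removes pseudogenes and genes whose only supporting DMCs are
cross-reactive probes. The rule is idempotent and independent of input row
order.

## The synthetic-array generator

No cohort data are distributable, so the package ships a generator whose
defaults encode the study conditions the pipeline targets:

* **Cohort**: 63 subjects; ages drawn as whole years uniform on 18–35 and
  re-drawn until the sample mean is within 0.6 years of 25.48 (closest
  attempt kept). Overweight status (BMI ≥ 25) follows a logistic model in
  age with slope +0.15/yr and marginal rate 0.318; patient status uses
  slope −0.25/yr and marginal rate 0.238. Only the marginal rates and
  association signs are calibrated; the logistic slopes are plausible
  round values.
* **Methylation states**: each probe belongs to UM/HM/FM with weights
  0.4695/0.1003/0.4302. Baseline beta is drawn from per-subgroup beta
  distributions with mean (concentration) 0.08 (100), 0.50 (12) and
  0.91 (100). The tight UM/FM archetypes keep mean-beta classification
  consistent with the drawn state (misassignment is negligible at the
  0.2/0.8 thresholds) and put the array-wide mean methylation near 0.48.
* **Age effects**: a configurable fraction of probes (default 3%)
  receives a linear age effect on the M scale, magnitude lognormal
  (median 0.04/yr, log-sd 0.4) or fixed, with subgroup-specific
  probabilities of a negative sign (0.9184/0.7473/0.5327) matching the
  observed direction split of age-associated CpGs. Effects are centred at
  the cohort mean age. Residual noise is Gaussian on the M scale with sd
  0.3.
* **Annotation**: probes are placed uniformly on chromosomes 1–22 and X
  (per-chromosome densities are not calibrated); island context uses
  proportions 0.3091/0.2300/0.0981/0.3628 for island/shore/shelf/open
  sea (the island and open-sea fractions are calibrated, the shore/shelf
  split is a typical array composition); SNP and cross-reactive flags at
  rates 0.15 and 0.06. Gene symbols are positional — probes in the same
  50 kb locus share a symbol — so genes are contiguous and ICRs
  (one per imprinted gene, anchored on one of its probes) provably
  contain at least one probe.

Determinism: a single master seed feeds per-component substreams
(covariates, annotation, beta matrix), so the same configuration always
yields a byte-identical fixture set; the seed is recorded in the fixture
manifest. Simulation studies inside the test suite draw their replicate
seeds once from a fixed base seed rather than using consecutive integers,
which showed overdispersed behaviour across replicate blocks.

What the generator does **not** emulate: probe type I/II chemistry and
normalization artefacts, batch or chip effects, correlated neighbouring
CpGs, population stratification, and realistic per-chromosome probe
density. Passing tests therefore demonstrate the statistical machinery
(unbiased estimation, FDR control, power at the configured effect sizes,
and correct bookkeeping through every stage), not robustness to those
real-data complications.

## Numerical and reporting choices

* Percentages are rounded half away from zero to 2 decimals at report
  time only; full precision is retained internally and in `*_full.csv`
  twins (statistics are rounded to 4 significant digits in the report
  CSVs).
* Constant probes give slope 0 and residual variance 0 rather than NaN;
  constant global means flag the correlation as undefined instead of
  propagating NaN.
* Tie-breaks in the top lists are deterministic: adjusted p, then raw p,
  then probe id.
* The Mann–Whitney U tests use the tie-corrected normal approximation
  without continuity correction, so strata with identical value multisets
  give p = 1.
* The outlier rule in the sensitivity rerun removes subjects whose global
  mean beta lies more than 3 MAD from the median — a conventional robust
  cut, since no specific rule is canonical. Dropping patients also drops
  the patient term from the design (it would be constant). The main
  analysis always keeps all subjects; exclusions are sensitivity checks.
* The pipeline's `run.log` carries stage banners without timestamps so
  that identical configurations produce byte-identical output trees;
  timestamps go to the console only.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to keep the full run
around two to three minutes while leaving Monte-Carlo error well below
the tested tolerances: FDR control uses 200 null replicates of
63 × 20,000 arrays; parameter recovery uses one 63 × 20,000 array with a
5% planted fraction at $\Delta M = -0.05$/yr and sd 0.3 (about 1,000
planted probes, so the standard error of the mean recovered slope is
roughly 2 × 10⁻⁴, far inside the ±0.005 tolerance); generator calibration
uses the default 63 × 50,000 array; identity properties use 10⁵ random
draws.

## A worked run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  synthetic = generator_config(n_subjects = 63, n_probes = 20000,
                               effect_fraction = 0.05,
                               effect_sizes = list(dist = "fixed", value = 0.05),
                               seed = 1),
  outdir = "run1")
bundle <- run_pipeline(cfg)
bundle$subgroup_summary
head(bundle$top)
```

## Known limitations

Region-level (DMR) calling, surrogate-variable/batch correction, GO
enrichment and IDAT-level preprocessing are out of scope. The biomarker
selection is only as good as the supplied gene lists: imprinted-gene
catalogues, ICR maps and disease databases are inputs, not curated by the
package, and the packaged 28-gene score card is a transcribed worked
example for regression-testing the scoring arithmetic, not a discovery
resource.
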