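---
title: "Models and methods behind methylaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylaging)
```

# The scientific problem

Comparative epigenomics asks two linked questions of cross-species DNA
methylation data: can the methylation state of conserved CpG sites predict
an individual animal's chronological age, and does the *rate* at which
methylation changes with age explain why some species live far longer than
their body size predicts? `methylaging` implements a complete analysis
chain for both questions — epigenetic clock fitting and cross-validation,
meta-analytic discovery of age-associated differentially methylated
positions (DMPs), phylogenetic regression of longevity on methylation
rate, mixed-model discovery of longevity-associated DMPs, and gene/region
enrichment — together with a synthetic-data generator that produces
datasets with known ground truth, so every stage can be validated
quantitatively.

The central container is the `MethylAgingExperiment`, a
`SummarizedExperiment` holding a beta-value matrix (methylation fractions
in $[0,1]$, probes × samples), probe annotation, per-sample metadata
(species, age in years, sex), a per-species trait table (maximum lifespan,
body mass, longevity quotient, longevity class) and a phylogeny whose tips
match the species names.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions used throughout the test suite and the acceptance script.

**Phylogeny and traits.** `simulateTree()` draws a random coalescent
topology and rescales it to an ultrametric tree of fixed depth.
`simulateSpeciesTraits()` evolves a Brownian-motion trait along the tree
and affine-maps it into the configured longevity-quotient (LQ) range
(default 0.8–5, spanning average to exceptionally long-lived mammals), so
related species have related longevity. Body mass is log-uniform on
5–1200 g (a realistic bat-like range), and maximum lifespan is
`LQ * a * mass^b` under the conventional nonflying-eutherian allometry
`a = 4.88, b = 0.153` — a simulation choice, configurable, and never used
as an analysis constant. Longevity classes are assigned by LQ terciles
(top third `long`, bottom third `short`, middle `unassigned`), with an
override for hand-picked class designs.

**Methylation trajectories.** Each probe belongs to an archetype:
`age_hyper`, `age_hypo`, `longevity`, `sex`, `unmapped` or `null`. Latent
methylation drifts on the logit scale,

$$\mathrm{logit}(\mu_{ps}) = b_{0p} + s_p \, r_{p,\mathrm{sp}} \,
\mathrm{age} + u_{p,\mathrm{sp}},$$

with direction $s_p \in \{+1, -1, 0\}$ and species rate
$r_{p,\mathrm{sp}} = \texttt{base\_rate} \cdot
\mathrm{LQ}_\mathrm{sp}^{-\texttt{rate\_lq\_exponent}} \cdot m_p$, where
$m_p$ is per-probe rate heterogeneity (uniform on $[2/3, 1.5]$).
Modelling drift on the logit scale keeps beta values bounded at any age;
in the small-slope regime the linear-scale rate is approximately
$r \mu (1-\mu)$, i.e. logit drift $\approx 4\times$ the linear slope at
$\mu = 0.5$. The default `base_rate = 0.03` logit units/yr and
`rate_lq_exponent = 1` make long-lived species drift proportionally
slower — the structure the PGLS stage is designed to detect.
Longevity-archetype probes instead drift at class-dependent rates
(short-lived `class_rate_ratio = 3` times faster than long-lived);
sex-archetype probes carry a 1-logit female offset; unmapped control
probes sit at 0.5 with no biology, emulating the behaviour of
non-aligning probes, which resemble SNP controls. Observed values add
Gaussian array noise (`noise_sd = 0.03` beta units, a typical array
technical SD) and clamp to $[0,1]$; per-probe, per-species random logit
offsets (`species_sd = 0.15`) emulate sequence-divergence effects.

**Sampling design.** Each species contributes a uniform 10–60 samples
(the spread seen in multi-colony field/captive studies) with ages uniform
on $[0, 0.8 \times \text{max lifespan}]$ — the oldest animal sampled is
essentially never the record holder; the within-species age distribution
is a modelling choice, not inferred from any particular study.

**Annotation.** Probes receive synthetic genes, signed TSS distances and
region categories honouring the promoter invariant (promoter ⇔ distance
in $[-10\,000, +1000]$ bp of the nearest TSS, transcription-direction
signed). Hypermethylating age/longevity probes get a 4-fold promoter odds
bias (`promoter_bias_hyper`), reproducing the promoter concentration of
hypermethylating sites reported for mammalian methylation arrays; set it
to 1 for a region-neutral null. Non-control probes map in each species'
genome with probability 0.9; unmapped controls map nowhere.

**What the generator does not emulate:** probe-level cross-hybridisation,
normalisation artefacts, batch effects, tissue heterogeneity, non-uniform
age sampling, CpG-island structure, and genomic coordinates beyond
category labels. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not robustness
to every artefact of real arrays.

# Quality control

`betaFromIntensities()` computes
$\beta = \max(M,0) / [\max(M,0) + \max(U,0) + 100]$ from the
methylated/unmethylated channel intensities; the offset keeps the ratio
defined and in $[0,1)$. `probeQCStats()` reports per-probe mean, SD
($n-1$ denominator) and CV in percent. `detectOutlierSamples()` screens
each species for samples whose mean correlation to their conspecifics
falls more than 3 robust SDs (median ± 3 × MAD × 1.4826) below the
species median — a deterministic, scale-free criterion chosen because
cluster-based outlier screens are not uniquely defined; species with
fewer than three samples are skipped. Normalisation is an explicit hook
(`normalizeBetas()`, off by default, optional per-sample quantile
normalisation) so the choice is visible rather than buried.

# The epigenetic clock

`fitClock()` regresses transformed age $y = \sqrt{\text{age} + 1}$ on
beta values by elastic net with mixing `alpha = 0.5` (the midpoint
between ridge and lasso, fixed rather than tuned) via glmnet. The penalty
is chosen as the minimiser of a seeded ten-fold internal cross-validation
error (the CV-minimum rule, not the 1-SE rule, matching the default
behaviour of automatic penalty selection); predictors are standardized
internally and coefficients reported on the beta scale. `predictAge()`
inverts the transform as $\widehat{\text{age}} = \max(\hat y, 1)^2 - 1$:
the clamp at $\hat y = 1$ (age 0) is the minimal choice that keeps
predictions nonnegative, since the inverse transform is otherwise
unconstrained. Model probes absent at prediction time are imputed at
training means (with a logged count); more than 20 % missing is an error.

`crossValidateClock()` supports leave-one-out (LOO) and
leave-one-species-out (LOSO) schemes. Every fold refits the entire model,
including penalty selection, and the per-fold predictor set is restricted
to probes mapped in at least one training species, so the held-out
species never leaks mapping information. Accuracy is summarised by the
Pearson correlation and the *median* absolute error between observed and
predicted age, both on the untransformed year scale (prediction plots are
conventionally drawn in years), plus per-species mean bias — in LOSO, a
species whose methylome drifts slower than the cohort is systematically
predicted too young, which is itself a longevity signal.

# Age DMPs by meta-analysis

Within every species with at least 15 samples, each probe's Pearson
correlation $r$ between beta and untransformed age is converted to a
Fisher deviate $z = \operatorname{atanh}(r)\sqrt{n-3}$, standard normal
under the null; the deviates are combined across species with Stouffer's
unweighted test $Z = \sum_i z_i / \sqrt{k}$. The Fisher construction was
chosen over p-value inversion because it is deterministic, monotone in
$r$, and exactly standard normal under the null. Probes constant within a
species are excluded for that species; exactly collinear probes
($|r| = 1$, possible in noise-free simulations) are clipped at
$|{\operatorname{atanh}}| \le \operatorname{atanh}(1 - 10^{-12})$ so they
rank at the top instead of producing non-finite deviates. Probes are
ranked by $|Z|$ (equivalent to two-sided $p$), with probe-identifier
tie-breaks for determinism, and the top `k = 2000` form the age-DMP set.
Direction is the majority sign of the contributing per-species
correlations; ties fall back to the sign of $Z$.

# Longevity and methylation rate (PGLS)

For every species with at least ten samples, the per-probe methylation
rate is the OLS slope of beta on age (beta-units/year); the species-level
summary is the mean slope over the hypermethylating age DMPs and,
separately, over the hypomethylating ones. Rates are kept *signed*, so
mean hypomethylation rates are negative; consequently the PGLS
correlation of LQ with the hypo rate is *positive* (long-lived species
have less-negative rates) — the same "long-lived species change more
slowly" effect, with the sign carried by the convention rather than the
biology.

`pglsFit()` solves generalized least squares under the Brownian
covariance $C_{ij}$ = shared root-to-tip path length (via `ape::vcv()`):
$\hat\beta = (X^\top C^{-1} X)^{-1} X^\top C^{-1} y$, residual scale
$\hat\sigma^2 = r^\top C^{-1} r / (n-p)$, two-sided $t$ tests on $n-p$
df, and the t-derived effect size $r = t/\sqrt{t^2 + \mathrm{df}}$ — the
standard conversion when an effect-size correlation is reported alongside
a GLS $t$. Rescaling all branch lengths leaves estimates and tests
unchanged. Both the headline model (`LQ ~ rate`) and the mass-adjusted
variant (`log(max lifespan) ~ rate + log(mass)`) are available. The LQ
itself (`computeLQ()`) requires explicit allometric coefficients; the
package deliberately ships no default allometry for analysis use.

# Longevity DMPs by mixed model

For the species with assigned longevity classes, each probe is fit by the
ML random-intercept model

$$\beta = b_0 + b_1\sqrt{\text{age}+1} + b_2\,\text{class} +
b_3\sqrt{\text{age}+1}\cdot\text{class} + u_\text{species} +
\varepsilon,$$

with class coded short = 1, long = 0, $u \sim N(0, \tau^2)$,
$\varepsilon \sim N(0, \sigma^2)$. The single variance ratio
$\tau^2/\sigma^2$ is profiled by bounded one-dimensional search on
$[0, 10^4]$ (tolerance $10^{-8}$, with the $\tau^2 = 0$ boundary
evaluated exactly); because the random effect is species-blocked, the
marginal covariance inverts in closed form per block, which makes
per-probe fits fast enough to run genome-wide. The interaction is tested
by a likelihood-ratio test against the no-interaction ML fit
($\chi^2_1$); the LRT was chosen over a Wald $t$ because mixed-model Wald
degrees of freedom are ill-defined, while two ML fits sharing the same
profiling scheme give a well-posed statistic. Non-converged probes are
excluded from the multiple-testing family with a logged count.

Interaction p-values are adjusted by Benjamini–Yekutieli FDR (valid under
arbitrary dependence, which correlated CpGs certainly exhibit), via
`stats::p.adjust(method = "BY")` behind `byAdjust()`. Significant probes
are classified by the signs of the age main effect and the interaction: a
positive interaction means a steeper positive slope in short-lived
species, so (+, +) is "short gains faster" and (−, −) is "short loses
faster"; the two discordant combinations, which the gain/lose rule does
not cover, are labelled "long gains faster" / "long loses faster" by
symmetry.

# Enrichment

`assignGenes()` maps DMPs to their annotated nearest gene (optionally
restricted to a region such as promoters) and calls a gene
hypermethylated when it has strictly more hyper than hypo probes nearest
its TSS, hypomethylated in the converse case, and `unassigned` on ties
(ties are excluded from directional lists). `overlapTest()` is the
one-sided upper-tail hypergeometric test
$P(X \ge k)$ for the overlap of two identifier lists within a background
universe (both lists intersected with the background first; odds ratio
from the 2×2 table with a 0.5 continuity correction when a cell is
empty); a two-sided Fisher variant is available by flag, but the
upper-tail form is the default because enrichment questions are
directional. `regionEnrichment()` tests hyper- and hypo-direction DMPs
separately against the background frequency of a region category.
External gene lists are consumed as one-symbol-per-line text files,
upper-cased; none are bundled.

# Pipeline and reproducibility

`runPipeline()` executes simulate/load → QC → clock CV → age meta →
rates → PGLS → longevity DMPs → enrichment with a single
`pipelineConfig()`, writing stage TSVs and a JSON manifest carrying an
md5 hash of the analysis-relevant configuration (output paths excluded),
the seed and per-stage summaries. One global seed is expanded into
per-stage child seeds by a fixed affine scheme, so toggling a stage never
shifts another stage's random stream; identical configurations reproduce
identical outputs byte for byte. All file formats are plain text:
tab-separated tables with `NA` for missing values, Newick with branch
lengths for trees.

# Numerical choices and problem sizes

* Fixed-penalty elastic-net fits use a warm-started path with convergence
  threshold $10^{-14}$, so the $\lambda = 0$ full-rank fit agrees with
  ordinary least squares to $10^{-6}$ and the $\alpha = 1$
  orthonormal-design fit matches the soft-thresholding closed form to
  $10^{-8}$.
* PGLS solves by Cholesky whitening; a non-positive-definite covariance
  or a rank-deficient whitened design is an error, not a silent fallback.
* The mixed-model profile search evaluates the $\lambda = 0$ boundary
  explicitly, so $\hat\tau^2 = 0$ data reduce exactly to OLS; constant
  responses return a degenerate fit with interaction $p = 1$.
* Validation problem sizes, chosen to exercise the method at realistic
  scale: clock cross-validation on 8 species × 25–40 samples × 2000
  probes; meta-analysis calibration on 5000 probes × 10 species;
  mixed-model calibration on 5000 probes × 8 species; PGLS calibration on
  500 replicates of a 20-tip tree and 50 full-pipeline replicates at the
  generator defaults (20 species, 3000 probes).

# Known limitations

Beta values are modelled with Gaussian noise rather than a bounded
likelihood, so heteroscedasticity near 0 and 1 is ignored (as it is in
the standard linear treatments this package mirrors). The mixed model
fits a random intercept only — no random slopes, no heteroscedastic
residuals. The Brownian covariance is the only phylogenetic model
(no Ornstein–Uhlenbeck or Pagel's λ). Probe mapping, annotation and
normalisation are consumed as inputs, not computed. The outlier screen
assumes most conspecific samples are mutually correlated and will not
flag coordinated batch artefacts.
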