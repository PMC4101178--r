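---
title: "Methods: genomic and marker-assisted prediction in hybrid rye testcross populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic and marker-assisted prediction in hybrid rye testcross populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ryegs)
```

## The problem

Hybrid rye breeding evaluates inbred line candidates through testcrosses: an
F3:4 line is crossed to an unrelated CMS tester and the resulting three-way
hybrid is grown in multi-location, multi-year yield trials. Genomic selection
(GS) promises to replace part of this expensive phenotyping by predicting a
candidate's testcross value from genome-wide markers; marker-assisted
selection (MAS) does the same from a handful of mapped QTL. How accurate
either route is depends on the trait's genetic architecture, the
heritability of the training data, the relatedness between the material used
to train the model and the selection candidates, and on how many locations
and years the training data cover.

`ryegs` implements the complete analysis chain for studying these questions
in two half-sib bi-parental populations (a shared parent P1 crossed to P2 and
to P3, 220 F3:4 lines each): a trial simulator, marker quality control,
two-stage REML phenotypic analysis, RR-BLUP and CIM-based prediction, and a
cross-validation engine covering genotype, environment, location and year
sampling schemes. Because the original field data are not publicly deposited,
the simulator is a first-class module: it generates data with the published
variance structure so that every downstream claim is testable.

## Phenotypic model

Plot values are analysed in two stages. Stage 1, within each location-year
environment:

$$y_{Env} = \mu 1_n + G\alpha_G + R\alpha_R + B\alpha_B + e,$$

genotypes fixed, replications and incomplete blocks random, giving
per-environment BLUEs of the testcross progenies; a second fit with genotype
random gives the within-environment genotypic and error variances and the
repeatability $r = \sigma^2_g / (\sigma^2_g + \sigma^2_e / n_{rep})$.
Stage 2 combines the per-environment BLUEs:

$$y = \mu 1_k + G\alpha_G + E\alpha_{Env} + F\alpha_F + e,$$

with genotype fixed for across-environment BLUEs (the response of genomic
prediction) or random for variance components. Heritability on an
entry-mean basis is

$$h^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{G\times E}/n_{Env} +
\sigma^2_e/(n_{Env}\, n_{Rep})},$$

and the share of environment-specific genetic variance is summarized by the
interaction ratio $\sigma^2_{G\times E} / (\sigma^2_G + \sigma^2_{G\times E})$.

All REML fits go through `lme4::lmer()` behind the `reml_fit()` surface; on
balanced designs these estimates coincide with the closed-form ANOVA
estimators, which the test suite uses as an independent oracle. With one
record per genotype and environment, the stage-2 residual is the *effective
error* of an entry mean, $\sigma^2_{G\times E} + \sigma^2_e / n_{Rep}$; the
two components are separated either by subtracting the stage-1 pooled error
(`step2_fit`) or in one pass from plot data by `varcomp_trial()`, which fits
genotype, environment, interaction, replication and block as random effects
directly. Negative variance proposals are handled by lme4's boundary REML
(clamped at zero).

```{r table1}
tab <- rye_variance_components()
gy <- tab[tab$population == "A" & tab$trait == "grain_yield", ]
heritability(gy$sigma2_G, gy$sigma2_GE, gy$sigma2_e, gy$n_env, gy$n_rep)
ge_ratio(gy$sigma2_G, gy$sigma2_GE)
```

## RR-BLUP

Genomic prediction treats all marker effects as random with a common
variance. With $y$ the across-environment BLUEs and $X$ the dosage matrix,
the mixed-model equations

$$\begin{pmatrix} 1'1 & 1'X \\ X'1 & X'X + \lambda I\end{pmatrix}
\begin{pmatrix}\hat\mu \\ \hat a\end{pmatrix} =
\begin{pmatrix}1'y \\ X'y\end{pmatrix}, \qquad
\lambda = m\,\frac{1-h^2}{h^2}$$

are solved after column-centring $X$, which makes the intercept orthogonal
to the markers; the marker effects and all predictions are invariant to this
choice (asserted against a dense solve of the raw equations). $h^2$ is the
heritability of the estimation set, re-estimated inside every
cross-validation replicate from its genotype-by-environment BLUE matrix.
Predictions are $\hat g = \hat\mu + X_{new,c}\hat a$ and are identical to
GBLUP with kinship $K = X_c X_c'$ at the matched variance ratio — a known
identity that serves as a second independent oracle. The solver uses the
$m$-dimensional marker system when $m \le 4N$ and the $N$-dimensional kernel
system otherwise; both paths agree to numerical precision.

## Marker-assisted selection

`cim_scan()` implements composite interval mapping by the regression
approach: background cofactors are chosen by forward stepwise regression
(entry threshold $p < 0.01$, at most $n/5$ cofactors — conventional choices,
both exposed as arguments), and at each position of a 1-cM grid the
phenotype is regressed on a putative-QTL regressor with cofactors within a
10-cM window around the tested position excluded. The regressor is the best
linear predictor of the QTL dosage from the two flanking markers with
correlations $1 - 2\theta$ under the Haldane map function; at a marker
position it reduces exactly to that marker's dosage, so a scan without
cofactors is exactly simple interval mapping. The score is
$LOD = (n/2)\log_{10}(RSS_{reduced}/RSS_{full})$, with detection at
LOD $\ge 3.73$ and peaks counted as distinct when separated by at least
20 cM (or on different chromosomes). MAS-QTL prediction regresses the
training phenotypes on the detected-QTL regressors; with no detection the
prediction falls back to the training mean and is flagged. MAS-NEUT draws
the same number of markers spread over the seven linkage groups (one per
group first, extras at random) and uses ordinary multiple regression.
Standardized MAS accuracy is $r_g = \sqrt{R^2_{CV}/h^2}$, capped at 1.

## Cross-validation schemes

All schemes split genotypes into five near-equal subsets, four forming the
estimation set (ES) and one the test set (TS); ES and TS genotypes are
disjoint in every replicate, which the engine asserts and the test suite
audits. Accuracy is $r_p$, the Pearson correlation of observed TS BLUEs with
predictions, and $r_g = r_p/\sqrt{h^2}$ with $h^2$ re-estimated from the ES.
The genotype schemes draw ES/TS within one population, across the pooled
populations (stratified by population by default), pooled-ES with
single-population TS, or train on the whole of one population and test on
the whole of the other. Environment-sampling CV draws $k$ of the nine
location-year environments per replicate and computes both ES and TS BLUEs
from those environments only; for $k = 1$ the estimation set's heritability
is not separable from the environment mean, so the stage-1 repeatability of
the drawn environment is used for the penalty. Location/year CV trains on
two random locations over both years (or one year at the four complete
locations) and tests either in the same environments or in the complementary
ones; environments named in `exclude_env` (by default the single incomplete
location-year of the nine-environment network) never enter a test set. Every
replicate re-randomizes both fold membership and, where applicable, the
environment selection.

## The simulator and what it does (not) emulate

Founders are fully homozygous: P1 carries the reference allele everywhere,
P2 and P3 carry the alternative allele at independently drawn subsets of
loci (40% and 60% by default, so the second cross segregates at more
markers, mirroring the published per-population marker counts), and the
tester is unrelated. Meiosis follows the Haldane model — crossovers as a
Poisson process on the centimorgan map, no interference — and each F3:4 line
is obtained by two generations of single seed descent from the F1, giving
the exact 3/8 : 1/4 : 3/8 genotype frequencies (heterozygosity 1/4) at
segregating loci. Testcross values are purely additive in the line dosage;
the tester contributes a constant absorbed into the trait mean, and no
dominance or epistasis is modelled.

Trait architectures are calibrated to the published population-A variance
components (`rye_variance_components()`), with 50 additive QTL by default
placed at randomly chosen segregating marker positions. QTL effects are
drawn Gaussian and rescaled so the realized genotypic variance within each
population equals the target exactly; this removes genetic sampling noise
from recovery experiments.

The genotype-by-environment deviation of a line is Gaussian with variance
$\sigma^2_{G\times E}$, but its composition matters. Interaction is a
genetic phenomenon — a genotype's environment-specific deviation is caused
by its alleles — so one half of the interaction variance (the `ge_genetic`
fraction, default 0.5) is realized as QTL-by-environment effects: each
environment draws its own deviation of every QTL effect, calibrated per
environment and population to its variance share. The other half is
line-specific non-genetic noise. The marker-linked half is what makes
prediction accuracy transfer poorly to new locations and years (models
trained in a set of environments learn those environments' allele effects),
while the non-genetic half is what makes additional environments keep
improving accuracy; with either share at 0 or 1 one of the two published
patterns would disappear. Purely non-genetic interaction cannot produce any
location/year transfer penalty at all for genotype-disjoint test sets, which
is why the split is not optional plumbing but part of the data-generating
model.

Field design is simplified relative to the real alpha-lattice: replications
and incomplete blocks (22 plots by default) are generic random effects with
variances defaulting to 0.1 and 0.25 times the plot-error variance;
incomplete-block connectivity and spatial trends are not modelled. Missing
genotype calls, genotyping error, dominant (presence/absence) marker scoring
and selection among lines are likewise absent unless introduced explicitly
(`dominant_view()` provides the lossy DArT-style coding). Passing tests on
these data therefore demonstrate the correctness and calibration of the
estimators under the stated model, not the field performance of GS in any
particular breeding program.

## Numerical choices and problem sizes

Random-number use is explicit: every simulation function takes a `seed`, the
cross-validation drivers seed once per run and consume the stream
sequentially (identical seeds give bit-identical results), and the pipeline
derives per-stage seeds from one root seed by fixed offsets. The closed-form
estimation-set heritability is clamped to [0.01, 0.99] so the RR-BLUP
penalty stays finite; degenerate replicates (zero-variance predictions or
observations) are excluded from summaries and counted rather than imputed.
LD r² for monomorphic markers is NA with a warning, never a silent zero.

The packaged test suite and the acceptance script run at study scale for the
population dimension (two populations of 220 lines, nine environments, two
replications) but with 60 markers per linkage group (420 in total, about
320 after QC) rather than the full published panel, and with 100–200
cross-validation resamples per scheme rather than 5,000 — choices made to
keep a complete run at desk scale; marker effects, variance-component
recovery and all qualitative orderings are insensitive to these sizes. The
`n_resamples` and marker-count arguments restore parity-scale runs when
wanted.

## Known limitations

The two-stage analysis carries no stage-1 standard errors into stage 2
(equal weighting), matching the published description but slightly
suboptimal under unbalancedness. Variance components for quality traits
(starch, pentosan) reproduce the printed heritabilities only approximately
when recomputed from the two-decimal published components; these rounding
artifacts are treated as out of scope. The CIM scan uses a regression
(Haley-Knott-style) approximation rather than a mixture likelihood, and the
residual heterozygosity of F3:4 lines is handled through the dosage coding
rather than explicit phase. MAS accuracies on real data depend on software
conventions (cofactor choices, CV implementation) that are not reproduced
here beyond the stated model.
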