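---
title: "Models and methods for birth-weight evaluation and genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for birth-weight evaluation and genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ibwgp` implements a complete genetic-evaluation and genomic-prediction
chain for individual birth weight (IBW) in pigs. This vignette explains the
models, the numerical choices, and what the synthetic-data generator does
and does not emulate.

## The trait and the model ladder

A piglet's birth weight confounds four sources of variation: its own
additive genes, the maternal genetic effect of its dam (uterine capacity,
placental efficiency), the non-genetic environment common to its litter, and
residual noise. Ignoring the maternal and litter terms inflates the direct
heritability severely, so the package fits a ladder of four animal models
and compares them by likelihood ratio:

* Model 1: direct additive only, `y = Xb + Z_a u_a + e`
* Model 2: + maternal genetic, `Z_m u_m` (indexed by each record's dam)
* Model 3: + common litter, `W c`
* Model 4: all three random terms

with `u_a ~ N(0, A sigma2_a)`, `u_m ~ N(0, A sigma2_m)` (no direct–maternal
covariance; a deliberate restriction matching the model set above, since the
four-model ladder never fits one), `c ~ N(0, I sigma2_c)` and
`e ~ N(0, I sigma2_e)`. Fixed effects are sex, parity of the dam and
contemporary group (year–season cohorts; the simulator uses
generation × season), plus the dam's litter size as a covariate — larger
litters mean lighter piglets, and failing to correct for litter size would
leak that relationship into the maternal variance.

The direct heritability is `h2 = sigma2_a / sigma2_p` with `sigma2_p` the
sum of all fitted components. Model comparisons report both the raw
log-likelihood difference `dLogL = LogL_full - LogL_reduced` and the
chi-square statistic `2 dLogL`; evaluation software in this field often
tabulates the former while the test uses the latter, so both are emitted.
Degrees of freedom equal the number of extra components, with no boundary
mixture correction — a simple convention, noted in the output, that is
conservative for selecting the full model.

## REML: absorption and direct maximisation

The restricted likelihood is maximised over the log variance ratios
`gamma_i = sigma2_i / sigma2_e` with `sigma2_e` profiled out analytically
(L-BFGS-B, relative tolerance 1e-8, ratios bounded in [1e-6, 1e4]; a ratio
pinned at the lower bound is flagged as a boundary estimate).

The expensive part of each likelihood evaluation is the sparse Cholesky
factorisation of the mixed-model coefficient matrix. At evaluation scale
(tens of thousands of records) most animals are phenotyped non-parents, so
the package evaluates the likelihood on a *reduced* system: the
breeding-value equation of every non-parent with a record is integrated out
analytically, its record contributing `(u_sire + u_dam)/2` to the linear
predictor with the Mendelian-sampling variance `d_i sigma2_a`
(`d_i = 0.5 - 0.25 (F_s + F_d)`, with the usual adjustments for unknown
parents) folded into a heteroscedastic residual. This is the classical
reduced animal model: an exact reparameterisation, not an approximation —
the restricted likelihood is identical, which the test suite verifies
against a dense-matrix evaluation of `log|V| + log|X'V^-1 X| + y'Py` to
1e-4. The reduced coefficient matrix spans parents + fixed effects +
litters only (~9,000 equations instead of ~50,000 at a 20,000-record
scale), making a full four-model ladder fit a matter of seconds to tens of
seconds per model.

An average-information update scheme was considered and set aside: its exact
trace terms require selected inversion of the coefficient matrix, which the
available sparse factorisations do not expose, and with at most three ratio
parameters a quasi-Newton search on the profiled likelihood converges in
around ten iterations anyway.

Standard errors come from the numerical observed-information matrix
(central differences on the variance-component scale, relative step 1e-4)
at the optimum; the heritability SE follows by the delta method. After
convergence the *full* mixed-model equations are assembled once at the
converged ratios to obtain fixed-effect solutions, breeding values for every
animal, and — via sparse column solves of the coefficient matrix for
requested animals only — prediction error variances and reliabilities
`r2_i = 1 - PEV_i / ((1 + F_i) sigma2_a)`.

## Deregression and weighting

Marker models should not be trained on EBVs directly: an EBV is shrunken
and contains parent information that would be double-counted. Each genotyped
animal's EBV and reliability, with its parent average `PA =
(EBV_s + EBV_d)/2` and `r2_PA = (r2_s + r2_d)/4`, define a 2x2
parent-average/individual mixed-model system whose prior precision is
`lambda [[4, -2], [-2, 2]]` (`lambda = (1-h2)/h2`), reflecting
`Var(g_PA) = sigma2_a/2` and `Cov(g_PA, g_i) = sigma2_a/2`. Solving that
system for the information content of the animal's own records yields
DEBVexcPA (deregressed, ancestral information removed) and its reliability;
DEBVincPA adds the parent average back. Two contracts pin the arithmetic
down and are enforced to 1e-10 in the tests: re-applying the 2x2 shrinkage
to DEBVexcPA reproduces the input EBV exactly, and
`DEBVincPA - DEBVexcPA = PA` by construction. Note the two reliability
scales in that system: the individual's reliability is measured against
`sigma2_a`, the parent average's against its own variance `sigma2_a/2`.
One consequence worth knowing: when an animal's reliability far exceeds its
parent average's, the system implies a *negative* parent-average
information content, and the deregressed reliability can then slightly
exceed the EBV reliability; whenever the implied parent-average information
is nonnegative, `r2_DEBV <= r2` holds exactly (verified over a 20,000-point
grid in the test suite).

Records with `r2 <= r2_PA` carry no own information and are excluded with a
reason; records with deregressed reliability below 0.01 (strict) are
filtered. The marker-model weight is
`w_i = (1 - h2) / ((c + (1 - r2_DEBV)/r2_DEBV) h2)`, where `c` is the
fraction of genetic variance not captured by markers — unknowable in
advance, defaulting to 0.5 and configurable.

## Weighted BayesB / BayesC

The marker model is `y_i = mu + sum_j Z_ij u_j delta_j + e_i` with
`Var(e_i) = sigma2_e / w_i` and the GenSel-style allelic coding −10/0/10
(heterozygote 0); columns are mean-centred by default so the intercept
absorbs the coding offset (centring is a toggle, since reasonable software
differs here). `pi` is the fixed prior fraction of excluded markers — 0.99
for medium-density panels, 0.999 for high-density, never estimated.

The single-site Gibbs sweep updates `mu`, each `(delta_j, u_j)` from the
marginal likelihood with the effect integrated out given its variance, then
the variances. BayesC uses one common effect variance for included markers;
BayesB draws a locus variance from its prior whenever the locus is currently
excluded (the canonical locus sampler). Priors are scaled inverse
chi-squares with 4 df; the marker-effect scale is set so the prior mean
total genetic variance matches a target (default: half the weighted response
variance), spread over the expected `(1-pi)` active markers on the coded
scale — `S2u = target (nu-2)/nu / ((1-pi) sum_j Var(Z_j))`. The default
chain is 110,000 iterations, 10,000 burn-in, thinning 5; tests and the
acceptance script use shorter, validated chains (2,500–30,000 iterations)
because their fixtures are far smaller than a production panel.

Correctness is enforced by three oracles rather than by convention: with
`pi = 0` the posterior mean effects must match a weighted ridge (SNP-BLUP)
solve; a single locus must match the conjugate closed form; and under a
prior-dominated null (tiny effect-variance scale, pure-noise response) the
inclusion rate must sit at `1 - pi`. Duplicating a record must be
posterior-equivalent to doubling its weight.

## Window scan and cross-validation

Posterior samples of the marker effects are decomposed over half-open 1-Mb
windows `[k Mb, (k+1) Mb)` per chromosome: for each saved sample the
variance across animals of the window's genetic values is divided by that of
the total genetic values, and GV% is the posterior mean of those per-sample
percentages (the ratio of posterior means is also reported; the per-sample
mean is the field's reporting convention). Sample variances use the n−1
denominator — the choice cancels in the ratio. Windows above 0.5% (strictly)
are flagged informative, with an option to also show the top-N windows
below the threshold; SNPs are ranked within windows by posterior model
frequency, ties broken by position.

Cross-validation folds come from k-means (k = 5, 10 restarts, fixed seed)
on the rows of the pedigree relationship matrix restricted to the genotyped
animals — the feature space is a design choice; clustering relationship
profiles groups relatives, which is exactly what minimising
training–validation relatedness requires, and it reproduces the
within/between-cluster summary statistics directly. Accuracy is the Pearson
correlation between DGVs (`Z u_hat`) and the response per fold; the
reported SE is the between-fold standard deviation over `sqrt(k)` — a
pragmatic convention, since fold accuracies are not independent.

## The synthetic-data generator

The generator's defaults are the study conditions the package targets:
variance components (0.009, 0.010, 0.017, 0.030) kg² — phenotypic 0.066
kg², direct h² 0.14 —, mean 1.372 kg, and a mean litter size of 11 piglets
(Poisson, floor 1), matching the range reported for the modern Korean
Yorkshire industry; the litter-size covariate slope defaults to −0.012 kg
per piglet, a realistic crowding effect. Fixed-effect level values for sex,
parity and contemporary group are drawn once from N(0, 0.05²) — a few tens
of grams, the order observed for such cohort effects. Each selected dam
produces two litters (two parities) per generation, which is what separates
the maternal genetic variance from the litter variance; with one litter per
dam the two are nearly confounded and only the relationship structure
identifies them. All randomness flows from one master seed through named
sub-streams, so each stage is reproducible independently.

Genotypes are gene-dropped: founder allele frequencies ~ Uniform(0.05,
0.95), Mendelian inheritance without mutation or selection, no linkage map
realism (positions are uniform draws; adjacent SNPs are unlinked). Direct
breeding values either come from `n_qtl` panel SNPs (effects scaled so the
realised variance equals `sigma2_a`; QTL stay in the panel by default, with
an option to mask them) or, without genotypes, from the recursive rule
`u_i = (u_s + u_d)/2 + m_i`. Maternal breeding values always use the
pedigree rule and are independent of the direct values (the evaluation
model's assumption); real populations may have a negative direct–maternal
correlation that the generator does not emulate.

Because the simulator realises exactly the variance structure the REML
models assume, passing recovery tests demonstrates the estimator and the
pipeline arithmetic — not robustness to model misspecification, selection,
genotyping error, or pedigree errors in field data.

## Problem sizes and numerical conventions

The test suite and acceptance script size their simulations so the whole
chain demonstrates the properties at desk scale: variance-component
recovery on ~20,000 records over 10 seeds (each component within two
empirical standard errors, full model selected by the ladder), the genomic
arm on ~1,000 genotyped animals with 1,000 SNPs and 10 QTL. Degenerate
inputs are errors, not guesses: records with unknown dams under a maternal
model, all-missing SNPs at completion, residual missing calls at recoding,
folds with fewer than three validation animals. Mode-completion ties break
to the smaller dosage, duplicate map positions keep the higher-call-rate
SNP, and the reliability filter is strictly "less than" — each a
deterministic reading of the corresponding rule.

## Limitations

Single-trait only; no direct–maternal covariance; no genomic or single-step
relationship matrices; `pi` is never estimated; imputation is a modal fill
(pedigree-aware imputation belongs to external tools); window variances use
physical 1-Mb bins, not LD-aware blocks. Absolute REML log-likelihoods are
convention-dependent (constants included consistently, so only differences
are meaningful across nested fits on the same data).
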