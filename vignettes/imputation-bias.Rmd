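---
title: "Reference-panel bias in genotype imputation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-panel bias in genotype imputation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Genotype imputation predicts untyped or masked SNP genotypes from typed
flanking markers and a phased reference panel, exploiting linkage
disequilibrium (LD). Common practice uses one healthy reference population
for every phenotype. When the query samples are disease cases, their risk
haplotypes are under-represented in a healthy panel, so imputation errors
are not symmetric: they systematically favour the non-risk allele. The
consequences are (i) an allele-directional *bias* at disease-associated
markers and (ii) *deflation* of odds ratios estimated from imputed
genotypes.

`imputebias` provides a fully synthetic, seedable test bed for this
phenomenon: a cohort simulator with block-like LD and a known risk
architecture, an exact diploid haplotype-copying imputation engine, and the
discordance/bias/deflation statistics needed to quantify the effect.

## Metrics

All statistics are defined on minor-allele copy counts, the minor allele
being determined from pooled case + control frequencies (ties at 0.5 go to
the alt allele). With `G0` the assayed ("true") genotype and a call
tolerance `T`, the imputed dosage `Gimp` in `[0, 2]` is called homozygous
major when `Gimp < T`, heterozygous when `1 - T <= Gimp < 1 + T`,
homozygous minor when `Gimp >= 2 - T`, and missing otherwise (`T = 0.5`
tiles `[0, 2]` completely and equals rounding).

* `D_M`: percent of evaluable samples where the call under-counts minor
  copies (major allele over-predicted); `D_m`: the minor analogue.
* `D_int = D_M + D_m`; `B_int = D_M - D_m`. Positive bias always means the
  major allele was over-predicted, and `|B_int| <= D_int` by construction.
* `D_frac = mean |Gimp - G0|`, `B_frac = mean (G0 - Gimp)` on the
  minor-copy scale (so `B_frac > 0` again means major over-prediction).
* OR deflation: per marker, logistic regression of case status on minor
  copies gives the true fit; the fit is repeated on imputed integer calls
  and on dosages, both oriented to the risk allele of the true fit, and
  `ratio = imputed OR / true OR` is reported on that oriented
  (`exp(|b|)`) scale.

Samples whose integer call is missing (possible when `T < 0.5`) are removed
from both numerator and denominator; every report row carries
`n_evaluated`.

Group summaries are reported as mean ± 2 × standard error, labelled as the
95% CI. Group contrasts use Welch/paired t-tests with rank-sum/signed-rank
tests in parallel, normality is probed by the Anscombe–Glynn kurtosis test
(implemented in-package), and bias directions use exact binomial sign
tests.

## The imputation engine

The engine is a Li–Stephens-style haplotype-copying hidden Markov model
made diploid by taking the hidden state to be an *ordered pair* of
reference haplotypes. Per haplotype and per inter-variant gap of `d` bp,
the copied template is kept with probability `exp(-rho d) +
(1 - exp(-rho d))/H` and switches to any given template with probability
`(1 - exp(-rho d))/H` (`H` = panel haplotypes). At a typed site the
observed unphased genotype is emitted by summing over the two phase
assignments, each true allele equalling its template allele with
probability `1 - epsilon`; missing observations emit 1. Posteriors at the
masked site come from exact forward–backward over the `H^2` pair states —
the "stay or jump to uniform" structure reduces each update to `O(H^2)`
via row/column sums — and the dosage is the posterior mean copy count.
Per-site rescaling keeps the recursion normalised; panels of 200
haplotypes over 500-site windows run without underflow. The implementation
is exact and deterministic (no MCMC), and is verified against exhaustive
copy-path enumeration on small instances to machine precision.

Window selection is purely positional: all typed markers within a 1 Mb
window centered on the query (the classical choice that captures the
r² > 0.2 LD neighbourhood); the window width is configurable.

Defaults: `rho = 2e-5` per bp, `epsilon = 0.004`, `T = 0.5` (0.3 and 0.1
exposed via config). `rho` is deliberately larger than the literal
recombination scale: with a founder-block simulator, a larger copying
switch rate makes the posterior average over more templates, which (i)
stabilises dosages against reference-panel sampling noise and (ii)
reproduces the frequency-pull behaviour of practical imputation samplers,
whose effective population-scaled switch rates are likewise much larger
than per-meiosis recombination. `epsilon` trades haplotype trust against a
slight pull of dosages toward 1; because the minor allele is the rarer
one, large `epsilon` produces an artificial minor-favouring bias while
integer calling at `T = 0.5` produces a major-favouring one — 0.004
balances the two against the simulator's mutation rate so that
non-associated markers show only the small (~1–2% `B_int`) inherent
major-allele preference seen in real data.

## The synthetic study

`sim_config()` / `experiment_config()` fix the study conditions; all
randomness flows from one master seed through named per-stage streams.

* **Haplotypes.** 30 founder haplotypes over 240 SNPs on 3 Mb (one variant
  per ~12.5 kb), founder alt frequencies uniform in (0.1, 0.5). A
  population pool of 6,000 haplotypes is generated by mosaic copying:
  template switches at `1e-5` per bp (mean segment ~100 kb, so each window
  spans several blocks) and allele flips at 0.008 per site. The switch
  rate controls how much of a masked allele is *taggable* from flanking
  markers; the flip rate adds within-background variation that no
  phenotype-blind panel can recover. Together they put integer
  discordance in the 30–37% range — deliberately on the noisy side, so the
  systematic bias is well resolved against panel sampling noise at desk
  scale; real SNP-chip studies sit nearer 15–20% with much larger panels.
* **Disease model.** 55 causal variants whose risk allele is the minor
  (alt) allele with per-copy log-odds `+log 2`, and 55 whose risk allele is
  the major (ref) allele (`-log 2` per alt copy). The intercept is
  calibrated so population prevalence is 10%. Cases and controls
  (600 + 600) are rejection-sampled from the pool. Risk-major variants are
  encoded by the sign of the effect rather than by alt frequencies above
  0.5, since alt is constrained to be the founder minor allele.
* **Covariates.** Sex ~ Bernoulli(0.5), age ~ Normal(60, 10), independent
  of genotype; they exist to exercise stratified splitting (phenotype ×
  sex × age-quartile strata; odd strata alternate the extra individual so
  arm totals match within one).
* **Panels.** Split-B controls (60 individuals), an equal number of
  split-B cases, and an external phenotype-agnostic panel (40 individuals)
  drawn from an independent mosaic pool of the same founders — the
  same-ancestry, healthy-population reference of common practice.
* **Markers.** GWAS on split A (unadjusted logistic regression, additive
  ranking by `exp(|b|)` with a genotypic 2-df fit carried alongside), top
  100 = DAM, bottom 100 = NAM; DAM stratified by fitted risk allele.

The experiment then mirrors the three-condition design: mask each marker
in split-A cases and impute from (a) the split-B control panel and (b) the
split-B case panel; mask each marker in the full cohort and impute from
(c) the external panel, on which OR deflation is computed.

What the generator does *not* emulate: ancestry/population structure
(and hence ancestry matching in splits), genotyping batch effects, the X
chromosome, indels/multi-allelic sites, and realistic allele-frequency
spectra. Passing phenomenon tests therefore demonstrate the *mechanism* —
panel mismatch produces anti-risk bias and OR deflation — not the
magnitudes expected on any particular real cohort.

## Numerical and design choices

* Exact forward–backward replaces Markov-chain samplers: deterministic at
  desk scale, no convergence diagnostics, exactly testable against
  enumeration.
* HWE: exact conditional test (standard, not mid-p; "no more probable than
  observed"), enumerated per variant in controls only; QC keeps
  MAF > 0.05, HWE p > 1e-6, call rate > 0.95, all strict.
* Logistic fits: `stats::glm` IRLS; perfect separation flagged
  (`|b| > 15` or SE > 50) and excluded from ranking/deflation; OR
  reported from the additive slope because a 2-df genotypic fit does not
  define a single ranking.
* Ranking ties: smaller additive p, then variant id — deterministic.
* `B_frac` uses `mean(G0 - Gimp)` on minor copies so that the sign
  convention (positive = major over-predicted) is independent of the
  stored coding.
* Dosages are serialised in the VCF `DS` field with 4 decimals; the
  file-based pipeline therefore reproduces the in-memory one to ~1e-4 in
  fractional metrics and exactly in integer ones.
* Deflation ratios are computed per marker on the risk-oriented OR scale;
  because `E[exp(X)] > exp(E[X])`, noisy per-marker fits inflate mean
  ratios upward — visible for NAM (centred slightly above 1) and for
  dosage-based fits, which is why the integer-call ratio is the headline
  deflation statistic.

## Problem sizes used by the tests and the acceptance script

The default `experiment_config()` (240 variants / 3 Mb, 600 + 600 cohort,
split-B panels of 60 and an external panel of 40 individuals,
100 DAM + 100 NAM, 1 Mb windows) is the
study the acceptance script and the phenomenon tests run end-to-end; a run
takes a few minutes on one CPU, dominated by the ~360,000 forward–backward
imputations. Unit and property tests use much smaller instances (tens of
variants, panels of ~10 individuals) chosen so that the whole suite stays
well inside a half-hour on one core.

## Known limitations

* The `O(H^2)` pair state space caps practical panels at a few hundred
  haplotypes; real tools use linear-state or sampling approximations to
  reach thousands.
* The mosaic generator's 30 founder lineages give a coarser haplotype
  spectrum than coalescent simulators; LD decay is block-like rather than
  smooth.
* Reference panels are phased truth haplotypes; phasing error, a real
  contributor to imputation error, is out of scope.
* No covariate adjustment in the association scans (the design is matched
  instead), and no multiple-testing machinery — marker selection is by
  rank, which is exactly what the bias experiment requires.
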