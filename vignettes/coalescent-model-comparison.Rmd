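---
title: "Comparing sweepstakes reproduction models on site-frequency spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing sweepstakes reproduction models on site-frequency spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepstakes)
```

## The scientific question

High-fecundity organisms can reproduce through *sweepstakes*: a few
individuals contribute most of the next generation. Two mechanisms produce
such skew. Under **random sweepstakes** a random individual occasionally hits
a jackpot of favourable conditions; under **selective sweepstakes** recurrent
positive selection repeatedly filters genotypes, so winners are ephemeral
and must be reassembled each generation. The two mechanisms — and the
no-sweepstakes null — leave different footprints in the genealogy of a
population sample, and hence in the unfolded site-frequency spectrum (SFS)
$\xi_1,\dots,\xi_{n-1}$: counts of polymorphic sites at which $i$ of $n$
sampled lineages carry the derived allele.

This package implements the three genealogical models, their exact expected
spectra, simulators, and the fitting and diagnostic machinery to compare
them on an observed SFS.

## The models

All three are exchangeable coalescents specified by merger rates
$\lambda_{b,k}$ — the rate at which a fixed $k$-tuple among $b$ ancestral
lineages merges:

* **Kingman** (no sweepstakes): $\lambda_{b,2} = 1$, larger mergers
  impossible. Optional exponential population growth enters as a
  deterministic time change of the pairwise intensity by $e^{\beta t}$,
  $\beta \ge 0$ the population-size-rescaled growth rate.
* **Beta$(2-\alpha,\alpha)$** (random sweepstakes):
  $\lambda_{b,k} = B(k-\alpha,\, b-k+\alpha)/B(2-\alpha,\alpha)$.
  The skew parameter $\alpha \in (1,2]$ measures jackpot size (smaller
  $\alpha$, bigger jackpots); $\alpha = 2$ recovers Kingman and $\alpha = 1$
  is the Bolthausen–Sznitman coalescent. The *haploid* Λ version lets the
  sampled $k$-tuple merge into one block. The *diploid* Ξ version models a
  single pair of highly fecund parents: participants of a large reproduction
  event descend from one of the **four parental chromosomes**, so each event
  splits its participants uniformly into four groups that merge
  simultaneously. Growth enters through the intensity factor
  $e^{(\alpha-1)\beta t}$, chosen so that the $\alpha = 2$ limit reproduces
  the standard Kingman growth model while the effect of demography
  *vanishes entirely at maximal skew* ($\alpha = 1$) — a property the test
  suite checks by comparing TMRCA distributions at $\beta = 0$ and
  $\beta = 10$.
* **Durrett–Schweinsberg** (selective sweepstakes): a neutral site linked to
  recurrent beneficial mutations that sweep to fixation. We implement the
  canonical one-parameter form $\Lambda(dy) = \delta_0(dy) + c\,y\,dy$,
  giving $\lambda_{b,k} = \mathbf{1}\{k=2\} + c\,(k-1)!\,(b-k)!/b!$. The
  compound parameter $c = \delta s^2/\gamma$ (sweep rate × squared selection
  coefficient / recombination rate) is the density of selection per map
  unit; its components are not separately identifiable and any
  proportionality constant in the underlying sweep approximation is absorbed
  into $c$. All recovery experiments in this package are self-consistency
  exercises and are insensitive to that constant. A fraction
  `f_genomewide` of sweeps (default 0) captures every lineage regardless of
  recombination, modelling chromosome-wide sweeps or bottlenecks; such
  events arrive at rate $f\,c$ while local sweeps contribute non-null
  mergers at rate $(1-f)\,c\,(H_b - 1)$, so $f = 0$ reduces exactly to the
  canonical model.

## Exact expected spectra

For any Λ-type rate table the expected branch lengths $E[B_i]$ subtending
$i$ of $n$ leaves follow from a first-step recursion on the block-counting
chain. From $b$ exchangeable blocks the total merger rate is
$q_b = \sum_k \binom{b}{k}\lambda_{b,k}$; a $k$-merger happens with
probability $\binom{b}{k}\lambda_{b,k}/q_b$, after which — by sampling
consistency — the process is again a Λ-coalescent on $m = b-k+1$
exchangeable blocks with one block of weight $k$ and $m-1$ of weight 1. A
branch subtending $j$ of the $m$ blocks therefore subtends $j-1+k$ leaves
with probability $j/m$ (it contains the merged block) and $j$ leaves
otherwise. The recursion is deterministic, $O(n^3)$, and numerically stable
through log-gamma rate evaluation; `expected_sfs()` handles $n = 200$
comfortably. The Kingman table reproduces the closed form $E[B_i] = 2/i$ to
$10^{-10}$ for all $n \le 100$, and the simulators reproduce the recursion
within Monte Carlo error — a dual-route check exercised in the tests.

Under infinite-sites mutation at rate $\theta/2$ per unit branch length,
$E[\xi_i] = (\theta/2)E[B_i]$; the normalized spectrum
$\phi_i = E[B_i]/\sum_j E[B_j]$ is free of $\theta$.

## Simulators

Genealogy simulation (compiled code, driven by R's RNG so `set.seed()`
reproduces every run) uses the jump-and-hold scheme: exponential waiting
times at total rate $q_b$, merger size sampled from the rate table, merging
tuple uniform. The diploid Ξ version samples the number of *participants*
$j$ with the Λ-Beta law — obtained by integrating lineage-capture
probability $y^j(1-y)^{b-j}$ against the event-size intensity — then
assigns participants uniformly to the four parental chromosomes; events in
which no chromosome receives two participants are null and simply thinned.
Growth uses the closed-form inverse of the integrated intensity, so no
discretization is involved. Merging tuples are chosen uniformly by index;
ties cannot arise.

The two-locus, two-sample extension of the selective-sweeps model tracks
ancestral material of two loci at scaled map distance $d$: background
pairwise coalescence at rate 1, recombination at rate $d/2$ per lineage
carrying both loci, and sweeps hitting a uniform position on a window
around the loci. Each sweep draws intensity $y$ (density $2y$) and captures
a lineage's copy of locus $\ell$ when a *shared* uniform falls below
$y\,e^{-|x-p_\ell|}$ — the shared uniform makes the two loci coalesce
together when $d = 0$. The exponential decay of capture probability with
map distance is this package's modelling choice for the locus-escape
mechanism; the arrival rate $cL$ over a window of length $L$ calibrates the
per-locus pairwise sweep coalescence rate to the single-locus value
$c\,B(2,1) = c/2$. Genome-wide sweeps arrive at constant rate $f\,c$
independent of the window, which produces the distance-independent
correlation plateau. Without sweeps the simulator reproduces the classical
two-locus Kingman correlation $(\rho+18)/(\rho^2+13\rho+18)$, which the
tests verify.

## Fitting

The summary statistic is the **logit of the normalized SFS** over the
unmasked, nonzero classes — scale-free in the counts and sensitive to the
whole shape (L, U or V) of the spectrum. Distance between observed and
candidate summaries is Euclidean; the fit score is its square (a residual
sum of squares on the logit scale), which also ranks families in
`run_model_comparison()`. The paper-style residual diagnostic is the
per-class difference of observed and expected logit frequencies with
delta-method standard errors
$SE_i = \sqrt{1/(S\phi_i) + 1/(S(1-\phi_i))}$ on the observed proportion
($S$ the number of segregating sites) and $\pm 1.96\,SE$, $\pm 2.576\,SE$
bands.

Two fitting engines share this summary:

* **Grid search** (default): deterministic wherever the exact recursion
  applies (Kingman without growth, haploid Λ-Beta, Durrett–Schweinsberg);
  Monte Carlo mean-of-replicates curves otherwise (diploid Ξ, growth
  models), with one fixed curve seed for all candidates so the distance
  profile is smooth (common random numbers). Default grids: $\alpha$ step
  0.01 on (1, 2), $c$ step 0.05 on (0, 20], growth step 0.5 on [0, 10].
* **Adaptive ABC-MCMC**: Gaussian random-walk proposals accepted iff the
  proposal lies in the uniform prior box *and* the simulated summary is
  within a tolerance of the observed one. The tolerance is fixed at the 5%
  quantile of a 1,000-draw prior-predictive pilot (the chain starts at the
  best pilot draw); the proposal scale is adapted on the log scale toward a
  10% target acceptance rate with decaying weight $t^{-2/3}$, so the scale
  — not the tolerance — absorbs the adaptation. Default priors:
  $\alpha \in (1,2)$, growth $\in (0,50)$, $c \in (0,50)$; all bounds are
  arguments. Monte Carlo simulators default to 10,000 single-locus
  replicates per proposal — enough to avoid zero classes (hence infinite
  logits) in the averaged spectrum at the problem sizes used here.
  Posterior location is reported as mean, median and mode, the mode being
  the argmax of a Gaussian KDE (Silverman bandwidth) on a 512-point grid
  spanning the prior, restricted to the span of the draws.

With a deterministic simulator the acceptance region is a fixed subset of
parameter space, and the adapted chain settles at the target rate: the
acceptance-rate check in the tests realizes 9–10% across seeds.

## Neutrality statistics and MK machinery

`neutrality_suite()` computes Tajima's $D$, Fu & Li's $D$ (original 1993
variance constants $u_D, v_D$ — two published variants exist; the original
is followed), the variance-normalized Fay & Wu's
$H = (\theta_\pi - \theta_L)/\sqrt{\widehat{Var}}$ (the unnormalized
$\theta_\pi - \theta_H$ is available by flag) and Zeng's $E$, with
Watterson-based $\theta$ and $\theta^2$ plug-ins throughout. Two numerical
facts are worth knowing when reading simulation output:

* the normalized statistics are only *approximately* mean-zero under
  Kingman neutrality: at moderate $\theta$ they carry an $O(0.1)$ negative
  bias (visible equally in reference simulators), so the package's null
  checks judge "near zero" against the $\pm 1$ scale on which the
  statistics are interpreted;
* under the selective-sweeps model the sign of $E[\theta_\pi - \theta_L]$
  depends on the sample size: it is slightly positive at $n = 20$ and turns
  negative — the familiar high-frequency-excess signature — at study-scale
  $n \approx 68$.

Sliding-window scans use half-open windows (100 kb, 20 kb step by default)
anchored at the first site, with empty windows retained as undefined rows.
The McDonald–Kreitman test reports $NI = (P_n/P_s)/(D_n/D_s)$,
$-\ln NI$ (natural log — so the genome-wide adaptive proportion is
$\alpha = 1 - e^{-m}$ for a mean $m$ of $-\ln NI$), $\alpha = 1 - NI$ per
gene, and the two-sided Fisher exact $p$ (minimum-likelihood enumeration,
via `stats::fisher.test`, cross-checked in the tests against a direct
fixed-margin enumeration). Tables with zero cells are flagged undefined
rather than silently corrected; a +0.5 Haldane correction is available
behind a flag, off by default.

## Synthetic data: what it does and does not emulate

The generators provide every input the analysis consumes:

* `generate_fragment_ensemble()` — independent single-locus genealogies
  standing in for short genomic fragments separated by large gaps (the
  defaults record a 25 kb / 500 kb layout). Independence *between*
  fragments mirrors the decorrelating gaps; ignoring linkage *within* a
  fragment is the main simplification relative to chromosome-scale data,
  along with Poisson mutations, no genotype-likelihood uncertainty, no
  missing data and perfect polarization. Passing tests therefore
  demonstrate correctness of the genealogical machinery and the fitting
  pipeline, not robustness to those data artefacts — except misorientation,
  which `misorient_sfs()` injects explicitly via
  $\xi_i' = (1-\varepsilon)\xi_i + \varepsilon\,\xi_{n-i}$ (count-conserving,
  composable), with `truncate_sfs()` masking the four classes most affected.
* `generate_mk_tables()` — independent Poisson cells with means chosen so
  the generative neutrality index is exact; the minimal model under which
  $NI$ is estimable (the study gives no generative model for these counts).
* `generate_study_bundle()` — the full bundle (ensemble, mean, bootstrap
  bands, site table, MK tables) plus a generating record sufficient to
  replay it bit-identically from its seed.

Bootstrap bands resample fragments with replacement (100 replicates by
default) and report mean ± 2 SD of the resampled classwise means.

## Numerical choices and degenerate inputs

* Zero and monomorphic classes are masked, never smoothed; logit of 0 or 1
  is `NA` by design and masked classes are excluded consistently from both
  observed and candidate summaries, with renormalization over the common
  support. An optional pseudo-count is deliberately *not* applied anywhere.
* All-zero spectra raise a degenerate-input error at normalization;
  $\theta = 0$ mutation dropping returns an all-zero SFS flagged degenerate.
* Rate tables are computed on the log-gamma scale; the Λ-consistency
  identity $\lambda_{b,k} = \lambda_{b+1,k} + \lambda_{b+1,k+1}$ holds to
  $10^{-10}$ for every implemented family.
* Truncation requires $n \ge 6$ (otherwise the retained support is empty)
  and is idempotent.
* Grid fits break distance ties at the smallest grid point (`which.min`);
  ABC chains are replayable bit-for-bit from their seed, and every
  stochastic generator takes a `seed` argument that restores the caller's
  RNG state afterwards.

## Problem sizes

The test suite and the reproduction script run at the sizes the analyses
were designed around: exact recursions up to $n = 100$, Monte Carlo checks
with 15,000–20,000 genealogies at $n \le 20$, ABC chains of 6,000
iterations, grid refits at $n = 68$ and $n = 71$ with 0.05 spacing in $c$,
and a 10,000-replicate Ξ-Beta refit at $n = 68$ with 0.01 spacing in
$\alpha$ — about a minute of compute for the script and a similar amount
for the full test suite on one CPU.

## Known limitations

* The selective-sweeps model is single-locus and essentially haploid: no
  diploid or multi-locus version exists in the literature, so genome-scale
  joint predictions (beyond the restricted two-locus extension) are out of
  scope, as are competing/simultaneous and soft sweeps.
* The two-locus extension's distance-decay form is a modelling choice (see
  above); its predictions should be read qualitatively (monotone decay,
  plateau under genome-wide sweeps).
* Growth enters the Beta family through one specific time change; other
  demographic histories require external expected spectra.
* Folded spectra, genotype likelihoods and BAM/VCF handling are outside the
  package's scope; inputs are polarized spectra (realSFS flat or CSV),
  per-site tables and MK count tables.
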