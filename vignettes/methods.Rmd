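---
title: "Methods: connectome-based prediction of sustained attention and its coupling with adolescent substance use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-based prediction of sustained attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sustattn)
```

`sustattn` implements a longitudinal task-fMRI analysis chain linking
sustained attention, its connectome signature, and adolescent substance use:
stop-signal-task (SST) behavioural metrics, generalized psychophysiological
interaction (gPPI) connectivity, connectome-based predictive modelling (CPM),
exploratory factor analysis (EFA) of Timeline-Followback (TLFB) items,
residualized Spearman association grids, and a three-wave bivariate latent
change score (LCS) model. Because the cohort data such an analysis needs are
access-restricted, the package ships a synthetic-cohort generator with known
ground truth; every stage is validated against it. This vignette records the
models, the tunable parameters, the numerical choices, and what the synthetic
validation does and does not establish.

## Stop-signal behaviour

The SST presents Go trials (left/right arrows) and unpredictable Stop trials
in which a stop signal follows after a staircase-tracked stop-signal delay
(SSD, 250–900 ms on a 50 ms grid; +50 ms after a successful stop, −50 ms
after a failed one). Sustained attention is indexed by the intra-individual
coefficient of variation, ICV = SD(Go RT) / mean(Go RT); lower is better.

Choices where the convention was open:

* **Sample SD** (denominator \(n-1\)) for ICV — standard for per-subject
  dispersion at a few hundred trials.
* **"Errors on Go trials"** = wrong-side responses + omissions + late
  responses; the inclusion rule excludes subjects with a Go error rate
  strictly above 20% or mean framewise displacement strictly above 0.5 mm.
* **ICV uses correct, on-time Go responses only**: omissions have no RT and
  error RTs are contaminated by a different process.
* **SSRT** defaults to the integration method (the p(respond|signal)
  quantile of the Go RT distribution, omissions replaced by the slowest
  observed RT, minus the mean SSD), the consensus recommendation for
  staircase designs; the mean method (mean Go RT − mean SSD) is kept as an
  option. Commission rates at the 0/1 boundary flag the estimate unreliable.

A note on the staircase's long-run behaviour, established with an
independent Markov-chain stationary-distribution computation and mirrored by
the simulator: a 1-up/1-down staircase only balances successes and failures
while it can move in both directions. With Go finish times
\(\mathcal N(500, 100^2)\) ms and SSRT 200 ms the psychometric midpoint sits
at SSD 300 ms, one step above the 250 ms floor; failures at the floor cannot
move the staircase further down, so failures outnumber successes and the
stationary success rate is ≈46%, not 50%. This is a property of the clamped
design, not of the implementation; empirical SST commission rates are
likewise not exactly 50%.

## gPPI connectivity

For each ordered ROI pair the seed BOLD series \(Y\) is regressed on

\[
Y=\beta_0+\beta_1 X_{\text{physio}}
 +\textstyle\sum_c \beta_c\,X_{\text{psycho}(c)}
 +\textstyle\sum_c \beta_{\text{ppi}(c)}\,[X_{\text{physio}}\!\ast\!X_{\text{psycho}(c)}]
 +\varepsilon ,
\]

with conditions \(c\) ∈ {successful stop, failed stop, go} for the go-trials
model (8 model coefficients) and {successful stop, failed stop} for the
successful-stop model (6). The PPI terms are built at the neural level:
deconvolve the target series with the canonical HRF, gate by the condition
boxcar, reconvolve. The design additionally carries 36 nuisance regressors
(3 translations, 3 rotations, white-matter/CSF/grey-matter means, their
backward-difference temporal derivatives, and the squares of all 18) and
discrete-cosine high-pass columns for a 128 s cutoff
(\(\lfloor 2\,n_t\,\mathrm{TR}/128\rfloor\) columns). The edge value is the
PPI coefficient of the condition of interest (go, or successful stop); the
ROI×ROI coefficient matrix is averaged with its transpose and the diagonal
zeroed.

Numerical choices:

* **HRF**: double-gamma (peak delay 6 s, undershoot 16 s, ratio 6, 32 s
  support), sampled at TR/16 and normalized to unit sum. On the TR grid the
  kernel is *bin-integrated* (the microtime kernel summed within each TR
  bin): point-sampling at bin starts would place the HRF's leading zero on
  the diagonal of the convolution operator and make it singular.
* **Deconvolution**: ridge-regularized least squares on a full
  discrete-cosine basis, with the ridge weight selected by generalized
  cross-validation per series; ties (the GCV profile is flat when the
  residual reaches the numerical noise floor, i.e. noiseless input) resolve
  to the smallest candidate weight, so noiseless series invert essentially
  exactly. The response of the final few time points falls beyond the run
  and is unrecoverable in principle; the synthetic generator therefore
  plants neural signals inside the operator's recoverable subspace.
* **Single-stage estimation**: nuisance and high-pass columns sit inside
  each pair GLM rather than being pre-residualized, keeping degrees of
  freedom explicit. The matrix builder projects the shared design block out
  once and fits the pair-specific columns by Frisch–Waugh–Lovell residual
  regression — algebraically identical to the full per-pair OLS (asserted
  in the tests to machine precision) and two orders of magnitude faster.
* **Boxcars**: condition regressors use the events' stated durations; the
  PPI gate is the boxcar sampled on the TR grid.

Two estimator properties worth knowing. First, with noise on the *modeled*
(seed) series the planted PPI coefficient is recovered without material
bias; noise on the *target* series instead enters the deconvolved regressor
and produces the errors-in-variables distortion (of order ±10% at
signal-to-noise 2) that affects every deconvolution-based PPI method — the
generator exposes `target_noise_sd` separately so this is measurable.
Second, single-run pair estimates carry a chance-correlation floor of
roughly 0.25 (both the smooth residual and the PPI regressor derive from
unit-scale neural signals, so the floor is scale-free and limited only by
the run's effective degrees of freedom); single-subject edges are therefore
not interpretable, and planted-edge recovery is asserted on subject-averaged
matrices, exactly as the cohort-level analyses aggregate.

## Connectome-based predictive modelling

Within every training fold: (i) each edge's partial correlation with the
phenotype, controlling age, sex, scan site (dummy-coded), mean FD, and
mode-centred PDS at wave 1, computed by double residualization + Pearson
with p from the t distribution on \(n-2-k\) df; (ii) edges with \(p<0.01\)
split by sign into positive and negative networks; (iii) network strength =
sum of a subject's selected edge values, combined = positive − negative;
(iv) OLS of phenotype on intercept + strength + covariates, applied with
frozen coefficients to the test fold. Validation: 10- or 5-fold CV repeated
50 times (performance = the mean over repeats of the correlation between
pooled out-of-fold predictions and the observed phenotype — the average of
per-repeat r, not pooled predictions), and leave-site-out CV with one fold
per site (site dummies are dropped there; a held-out site's dummy would be
unidentifiable in training). Consensus edges are reported at two levels:
fraction of all folds (mask at ≥95%) and, for the repeat level, selection in
≥95% of a repeat's folds in ≥95% of repeats — both because the reference
convention ("48 of 50") is ambiguous between them. Permutation inference
shuffles the phenotype-to-connectome correspondence and reruns the whole
pipeline (one-sided \(p=(1+\#\{r_{\text{null}}\ge r\})/(n_{\text{perm}}+1)\);
skill is directional). Cross-wave/external transfer freezes both masks and
coefficients; the target wave supplies its own covariate values, with
covariates absent there (mode-centred PDS after wave 1) entering at 0, their
centred reference; significance shuffles the predicted values. Test-fold
predictions use training-frozen covariate coefficients (refitting them on
test covariates is offered nowhere — the frozen model is the paper-faithful
default and the only leakage-safe one).

## Substance-use factor structure

TLFB 30-day consumption counts (six items at wave 1: two each for alcohol,
cigarettes, cannabis; nine at waves 2–3 with cocaine, ecstasy, ketamine) are
screened (near-zero SD; per-item KMO < 0.5 removed worst-first), tested for
sphericity (Bartlett: \(\chi^2=-(n-1-(2p+5)/6)\ln|R|\), df \(=p(p-1)/2\)),
decomposed by principal components with the Kaiser eigenvalue > 1 retention
rule, varimax-rotated with Kaiser normalization, and scored by the
regression method (\(ZR^{-1}L\); scores centred by construction). The
rotation wraps `stats::varimax` but restarts it from several fixed
orthogonal rotations and polishes with closed-form pairwise angle sweeps,
because the SVD iteration stalls on symmetric saddle points (equal
within-block loadings) and can stop slightly short of the optimum — the
tests compare against a brute-force angle grid. Correlation input (not
covariance); a Spearman option exists for heavy-tailed counts.

## Associations and trajectories

Attention measures (ICV; network strengths) and factor scores are
residualized on their wave's covariates (age, sex, site, mean FD for brain
measures, mode-centred PDS at wave 1) and associated by tie-aware Spearman
correlation (p via the t approximation) over all wave pairs; one
Benjamini–Hochberg family per measure–factor grid at \(q<0.05\) (the
per-panel family matches how such grids are reported; composition is an
argument). Complete cases only — the reference design follows one sample
across waves. Quintile trajectories split subjects into five near-equal
groups on a baseline measure (rank-based; >40% ties at a boundary is an
error) and summarize top and bottom groups per wave with normal 95% CIs;
polarity labels map higher ICV / higher positive-network strength to *Low*
sustained attention and higher negative-network strength to *High*.

## Bivariate latent change score model

For constructs \(x\) (substance factor) and \(y\) (attention measure)
observed at three waves,

\[
\Delta x_{t\to t+1}=\alpha_x+\beta_x x_t+\gamma_2 y_t+\zeta_x,\qquad
\Delta y_{t\to t+1}=\alpha_y+\beta_y y_t+\gamma_1 x_t+\zeta_y ,
\]

with \(\gamma_1\) the lagged effect of substance use on attention and
\(\gamma_2\) the reverse. Self-feedback, couplings, and change-residual
(co)variances are constrained equal across the two intervals; wave-1
moments and change intercepts are free: 14 parameters against 27 observed
moments, 13 df. This is the minimal identified bivariate LCS; the exact
residual constraints of the reference analysis are not recoverable from its
text, so validation rests on recovery of this package's own generative
model. Covariates (age, sex, site) are residualized out of the observed
scores per wave before fitting; complete cases (no FIML).

Estimation minimizes the normal-theory discrepancy
\(F=\ln|\Sigma(\theta)|+\mathrm{tr}(S\Sigma^{-1})+(\bar
x-\mu)'\Sigma^{-1}(\bar x-\mu)-\ln|S|-p\) with `nlminb` from a moment-based
start plus jittered restarts (5 by default); variances are log-parameterized
and inadmissible points (non-PD blocks) are rejected, not clipped. PORT's
"false/singular convergence" returns are accepted when the solution is
admissible — they signal tolerance breakdown at an optimum. Standard errors
come from the inverse observed information (numerical Hessian of
\((n/2)F\)); standardized couplings scale by the implied predictor SD over
the implied first-interval change-score SD (their SEs by the same factor — a
delta-method simplification that ignores the scaling's own sampling
variance). Fit indices: \(\chi^2=(n-1)F_{\min}\); CFI against the
independence baseline (diagonal covariance, free means, 15 df); RMSEA
\(=\sqrt{\max(\chi^2-\text{df},0)/(\text{df}\,(n-1))}\); SRMR over the
correlation-standardized residual lower triangle including the diagonal.
The 10-model battery (2 substance factors × 5 attention measures) applies
one BH family to its 20 cross-lagged p-values; the reference family is not
stated, so this is documented as the package's choice.

## The synthetic cohort

The generator emits everything the pipeline consumes, as a pure function of
(config, seed). Defaults are the desk-scale study conditions:

* 200 subjects, 60 ROIs (1770 edges), 3 waves, 8 balanced sites;
* a unit-variance latent attention trait evolving with autocorrelation 0.5
  across waves; ICV per wave is a deterministic affine transform of the
  trait calibrated to (0.234, 0.038), (0.224, 0.051), (0.217, 0.052) —
  because ICV carries no extra noise, inter-wave ICV rank stability equals
  the configured trait stability;
* 20 positive + 20 negative planted edges at effect r = 0.32 (plus
  \(\sqrt{1-r^2}\) noise), null edges unit noise, per-site additive offsets
  (SD 0.1). The effect size is "≈0.3" with headroom chosen *a priori* by a
  power calculation: consensus selection demands per-fold significance at
  \(p<0.01\) in ≥95% of 500 folds, which at n = 200 needs the planted
  correlation two SEs above the fold-level selection threshold (≈0.20);
  r = 0.32 puts the expected per-edge consensus probability near 0.9,
  r = 0.30 near 0.83;
* covariates (age, sex, lognormal mean FD, wave-1 PDS) independent of the
  trait, so they are pure adjustment load;
* substance factors following the LCS equations (defaults \(\gamma_1=0\),
  \(\gamma_2=0.12\) — the magnitude of the reported ICV→Cig+CB coupling —
  self-feedback −0.2, change-residual variance 0.25, i.e. change noise at
  half the trait SD, so the coupling SE at n = 1000 is ≈0.012 and recovery
  within ±0.04 is comfortably testable); alcohol and drug factors correlate
  0.45 with Cig+CB (substance use co-occurs; without that cross-correlation
  the two-item alcohol block would fail the KMO ≥ 0.5 retention rule that
  real TLFB items pass);
* TLFB counts as rounded lognormal transforms of the factors (loading 0.9,
  item noise 0.45; intercepts graded so drug items are mostly zeros), giving
  heavy tails and exact zeros;
* fMRI time series (the slow path exercising the gPPI chain): band-limited
  neural signals projected onto the convolution operator's recoverable
  subspace, HRF convolution, condition-gated planted couplings, 9 base
  nuisance signals loading weakly on every ROI, white noise. The fast path
  draws edge matrices directly for CPM-scale work.

What the generator does **not** emulate: scanner noise spectra and
physiological artifacts; spatial autocorrelation of a real atlas;
right-skewed RT distributions and strategic slowing (its race model is
Gaussian); measurement error in ICV; missingness. Consequently, passing
tests show that the estimators recover the structures they target under the
assumed models at desk scale — they do not show that the restricted-cohort
effect sizes would reproduce. The planted effects are deliberately strong
(predictable ceiling r ≈ 0.88 for the combined network) so that recovery is
a sharp test; the reference analysis's CV correlations (≈0.2–0.4 at
n ≈ 700–1100) live in a much weaker-signal regime that desk-scale runs
cannot and do not claim to reproduce.

## Problem sizes and determinism

The shipped analyses and tests run at: cohort 200 × 1770 edges (CPM, 50 × 10
folds); permutation calibration at 60 subjects × 105 edges with 199
permutations × 200 outer replicates; LCS recovery at n = 1000 × 100 seeds;
EFA recovery at n = 1000 × 20 seeds; gPPI recovery at 300 time points × 100
replicates — sizes chosen so the whole suite completes on a single CPU in
minutes while keeping every assertion's Monte-Carlo error far below its
tolerance. All randomness flows through explicit seeds; identical seeds give
bit-identical outputs (asserted in the tests).

## Known limitations

* Deconvolution-based PPI attenuates/inflates under target-series noise
  (see above); no correction is applied — prototypes of Fuller-type and
  posterior-EM corrections proved fragile to the implicit prior and are not
  shipped.
* The LCS structure fixes equality of dynamics across intervals and has no
  measurement model; two-wave designs are rejected rather than special-cased.
* Leave-site-out CV cannot adjust for site; site-confounded phenotypes will
  leak site variance into the performance estimate (the residual-correlation
  transfer mode exists for exactly that situation).
* BH-FDR families are a reporting choice; changing family composition
  changes which cells clear q = 0.05.
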