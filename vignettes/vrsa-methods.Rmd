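---
title: "Methods: pattern component modelling of reach-planning fMRI designs"
author: "vrsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pattern component modelling of reach-planning fMRI designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrsa)
```

# The experimental design

Eight trial types arise from placing the initial hand (H), the target
(T) and the gaze fixation (E) on the left or right of a task board.
Because the six LEDs are collinear and symmetric about the board
centre (hand pair 2.3 cm apart, target pair 6.9 cm, gaze pair
32.9 cm), every element pair is at one of two distances: "near" when
the two elements share a side, "far" otherwise.  `trialTypes()`
enumerates the factorial with the forced near/far levels and
`boardDistances()` derives the metric distances from the LED
coordinates (±separation/2).

A functional run is 40 trials — five per trial type — with 60% go
trials.  Delay durations {1, 2, 4, 8, 16} s and target (plan)
durations {4, 6, 8} s are allocated by largest-remainder rounding of
the stated proportions ([0.52, 0.26, 0.13, 0.06, 0.03] and
[0.56, 0.30, 0.14]); remainder ties resolve toward the shorter
duration, giving delay counts {21, 11, 5, 2, 1} and plan counts
{22, 12, 6}.  Go/no-go labels are assigned *within* trial type (3 go +
2 no-go of each type's five trials): with unstratified assignment
nearly half of random runs would leave some condition without any
no-go trial and hence an all-zero regressor in the no-go GLM, while
stratification preserves the 24/16 overall split exactly.  After the
go/no-go cue, no-go trials close with the 2.5 s feedback window and
go trials with a nominal 1 s movement, each followed by a 1 s gap
(the movement duration is not stated by the design and only affects
nuisance regressors).

## Design matrices and the VIF

Planning activity is modelled in two separate GLMs per run: a 2 s
boxcar at target onset (early epoch) and the 2 s ending at the
go/no-go cue (late epoch), one regressor per trial type on no-go
trials.  Go-trial planning (same epoch windows) and go-trial movement
(1 s after the cue) enter pooled nuisance regressors; an intercept
completes the model.  Boxcars are convolved with a canonical
double-gamma HRF (response gamma shape 6, undershoot shape 16,
ratio 6, no derivative terms) on a 16× oversampled grid and sampled at
TR = 0.45 s.

The variance inflation factor of a design is the mean, over selected
regressors, of [(XᵀX)⁻¹]ᵢᵢ·(XᵀX)ᵢᵢ — each weight's estimation variance
in the joint model relative to estimating that regressor alone; it
equals 1 exactly for orthogonal regressors.  *Which columns enter the
mean was genuinely open.*  We compute the mean over the eight no-go
condition regressors, evaluated in the full joint model (so nuisance
collinearity still inflates them).  The alternative — including the
pooled go-planning regressor in the mean — has an irreducible floor
far above the study's bound of 1.15, because the late planning epoch
of every go trial abuts its movement window and the two nuisance
regressors are near-collinear by construction, which no trial ordering
can repair; the bound is only meaningful for the weights the analysis
consumes.  `optimizeDesign()` scores each candidate run by the worse
of its two epochs' VIFs and keeps the argmin; candidates stream from a
single RNG sequence, so the achieved VIF is non-increasing in the
number of candidates under a fixed seed.  With 200 candidates the
optimiser reliably lands near 1.12, below the 1.15 bound.

# The pattern component model

For one subject and region, the condition-by-voxel beta matrix *U*
(no-go conditions only, runs pooled by averaging each condition's
pattern — concatenation is available) yields the second-moment matrix
*G = UUᵀ/n*.  The model treats voxels as i.i.d. zero-mean Gaussian
8-vectors with covariance

$$\Sigma(h) = \sum_c e^{h_c} G_c + e^{h_0} I_8 .$$

The six hypothesis matrices $G_c$ are trace-one outer products of ±1
contrasts: the three direction contrasts are the factorial's main
effects and the three distance contrasts its two-way interactions, so
all six are mutually trace-orthogonal, and together with the constant
vector and the three-way interaction they form a complete Hadamard
basis of condition space.  Orthogonality is what lets a moment
projection of the sample *G* onto each $G_c$ serve as an unbiased
independent estimator in the test suite.

## Centering and the contrast subspace

The shared-mean pattern is not among the components, so *U* is
centered per voxel (across conditions) by default.  Centered data
carry no information along the ones vector, and their noise covariance
is the *projected* identity, not the identity: fitting an isotropic
noise term in the full 8-dimensional space to centered data is
mis-specified and biases every component weight.  The fit therefore
works in the 7-dimensional orthogonal complement of the ones vector
(a fixed orthonormal basis *B*): *S₇ = BᵀSB*, *G₇,c = BᵀG_cB* (still
trace one, since every contrast is orthogonal to the mean), and the
projected noise component is exactly *I₇*.  With `center = FALSE` the
model lives in all 8 dimensions and an explicit "mean" component can
be appended (`componentModels(includeMean = TRUE)`).

## Variational ReML

Log-scale weights enforce positivity.  With independent Gaussian
hyperpriors $h \sim N(-3, 16)$ — weakly informative: $e^{-3} \approx
0.05$ on the unit-variance scale of the generator, with a ±8 log-unit
2-SD range — Fisher scoring maximises the penalised log-likelihood
$J(h) = L(h) - \tfrac12 (h-\eta)^\top C_p^{-1} (h-\eta)$ with expected
information $\mathcal I_{kl} = \tfrac n2 \mathrm{tr}(\Sigma^{-1}
\dot\Sigma_k \Sigma^{-1} \dot\Sigma_l)$, a trust-region clamp of 8 log
units per step and step halving whenever a step would decrease $J$;
convergence is declared when the improvement falls below `tol = 1e-4`
(`maxIter = 128`; hitting the cap flags, not raises).  If the initial
$\Sigma$ at the prior mean is not positive definite the noise term is
lifted to the data scale ($\log(\mathrm{tr}(S)/p)$) before iterating.
The free energy at the mode is the Laplace evidence $F = J +
\tfrac12(\log|C_q| - \log|C_p|)$ with $C_q$ the inverse of the
penalised information.  The core runs in compiled code
(RcppArmadillo); a single 7-component fit on an 8×8 second moment
takes well under a millisecond, which is what makes the permutation
machinery below cheap.

## Scoring components

`componentEvidence()` reports, per component, $\Delta F = F_{\rm
reduced} - F_{\rm full}$ with the component's prior pinned "off"
(mean −32, variance 10⁻⁶): more negative means the data need the
component.  Two routes are implemented:

* `"bmr"` (default): the analytic Gaussian model-reduction identity on
  the full posterior, the route used by the established SPM-style
  pipeline this package follows;
* `"refit"`: an explicit refit under each reduced prior.

These agree only when the log-likelihood is close to quadratic between
the posterior mode and the pinned value.  For a strongly supported
component the mode sits ~30 log-units above −32 and the quadratic
extrapolation overshoots the true evidence loss by orders of
magnitude; for idle components the refit confirms that removal costs
essentially nothing (|ΔF| ≲ 3) while BMR can still report large
values.  This is an inherent property of Laplace BMR in
log-hyperparameter space, not a numerical problem — and it is exactly
why the credibility decision below never interprets raw ΔF magnitudes
but always calibrates them against a shuffle null built with the same
scoring route.  Group-level evidence is the fixed-effects sum of
per-subject ΔF (log evidences add across independent subjects).

# The shuffle null and the credibility criterion

`shuffleNull()` draws K permutations of the eight condition labels
(with replacement from the 8!−1 non-identity permutations; one
permutation per iteration, shared across subjects so the group
statistic stays exchangeable), relabels each subject's second moment,
refits, rescores, and sums over subjects.  The identity permutation is
evaluated first through the *same* arithmetic path as the single-fit
API, so the "real" entry reproduces the unshuffled pipeline bit for
bit.  Log Bayes factors are $\mathrm{LBF}_k = \Delta F_{\mathrm{shuf},k} -
\Delta F_{\rm real}$; positive values mean the true labelling carries
more evidence.

A component is credible at level $\alpha \in \{0.80, 0.95\}$ when

$$\mathrm{median}(\mathrm{LBF}) \;\ge\; \ln 3 \; + \;
  \text{(the } \lceil \alpha (K{+}1) \rceil\text{-th order statistic of
  the null strengths)},$$

where null strengths are the shuffled log evidences measured against
their own median, oriented so that *larger = stronger* (strong effects
are the most negative ΔF).  Two numerical choices matter here.
First, orientation: the null of ΔF is strongly left-skewed, so taking
the quantile on the weak side would understate the strongest effects
and inflate false positives several-fold.  Second, the finite-K
estimator: an interpolated sample quantile of K draws sits below the
population quantile, making the test anti-conservative
($P(\text{real} > \hat q_{0.95}^{\,\rm type7}\ \text{of 200 draws}) =
11/201 > 0.05$ under exchangeability); the $\lceil \alpha(K{+}1)
\rceil$ order statistic is the standard exact-permutation convention
and guarantees $P \le 1-\alpha$ before the ln 3 offset even applies.
A degenerate (constant) null reduces the rule to
$\mathrm{median}(\mathrm{LBF}) \ge \ln 3$.  Reported intervals are
empirical shortest-window HDIs.

# The synthetic generator

`generativeSpec()`/`generatePatterns()` draw each voxel's 8-vector
independently from $N(0, \sum_c w_c G_c + \sigma^2 I)$ — exactly the
exchangeable-voxel model the fit assumes — with optional lognormal
between-subject jitter of the weights (off by default) and optional
HRF-level simulation via `generateBold()` (time series = design matrix
× amplitudes + white noise).  Defaults mirror the study conditions:
27 subjects, 6 runs, and a planted structure of gaze-centric distance
(ET, weight 2) and target direction (T, weight 1) on unit noise —
direction-plus-distance encoding of the kind the experiment was built
to detect, at an effect size a mid-sized ROI plausibly shows.  The
`"tiny"` fixture (4 subjects × 2 runs × 200 voxels) keeps every
end-to-end test in seconds; `"paper_scale"` (27 × 6 × 2000) matches
the study dimensions.

What the generator does *not* emulate: spatial voxel correlation,
temporal autocorrelation and scanner drift, motion artefacts (the
original pipeline down-weights noisy volumes; this package uses plain
OLS on synthetic data), and between-region heterogeneity.  Passing
tests therefore certify the statistical machinery under its own
assumptions — recovery, calibration, type-I control — not robustness
to real fMRI noise.

# Test problem sizes

The suite validates the fit against a brute-force profile-likelihood
grid search (exact in the Walsh basis) on 1- and 2-component toys at
5000 voxels; parameter recovery at {500, 2000, 10000} voxels (RMSE
decreasing, 10% accuracy at 10000); type-I control of the 95%
criterion on 600 pure-noise tiny fixtures with K = 200 shuffles
(600 rather than 200 fixtures keeps the Monte-Carlo error of each
per-component rate near 0.009, small against the 0.075 bound); and a
power curve over planted weights {0.5, 1, 2, 4} at 40 fixtures each.
The full suite runs in a few minutes on one CPU.

# Known limitations

* Raw ΔF magnitudes from the default BMR route are only meaningful
  relative to their shuffle null; use `method = "refit"` when an
  absolutely scaled evidence loss is needed.
* The group model is fixed-effects; subjects with more voxels weigh
  more through their likelihoods, and no between-subject variance is
  estimated.
* Univariate noise normalisation of betas, cross-validated G
  estimators and random-effects group inference are out of scope.
* Direction components are interpretationally confounded (absolute vs
  relative frames) by the design itself; the package names them by
  the element whose side code they carry.
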