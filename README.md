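# vrsa: variational RSA / Bayesian pattern component modelling for reach-planning fMRI

`vrsa` implements the statistical pipeline of a delayed reach-to-target
fMRI study in which hand, target and gaze position each take a left or
right location on a task board (a 2×2×2 factorial, eight trial types).
The scientific question is *which movement parameters a region's
multivoxel activity pattern encodes during motor planning*: the
direction of the target (T), initial hand (H) and gaze (E), and the
relative distances between hand–target (HT, body-centric), gaze–target
(ET, gaze-centric) and hand–gaze (HE).

## The model

For one region and subject, the eight condition activity patterns form
a condition-by-voxel matrix *U* whose second-moment matrix

&nbsp;&nbsp;&nbsp;&nbsp;*G = U Uᵀ / n*<sub>voxels</sub>

summarises pattern similarity between conditions.  The pattern
component model decomposes *G* as a non-negative weighted sum of
hypothesis components plus isotropic noise,

&nbsp;&nbsp;&nbsp;&nbsp;Σ(h) = Σ<sub>c</sub> e<sup>h<sub>c</sub></sup> G<sub>c</sub> + e<sup>h₀</sup> I₈,

where each *G<sub>c</sub>* is the trace-one rank-one outer product of a
±1 contrast over the eight conditions (direction components carry one
element's side code; distance components carry the product of two side
codes, +1 = near).  Treating voxels as i.i.d. zero-mean Gaussian with
covariance Σ(h), the log-scale weights *h* are estimated by variational
ReML (Fisher scoring on a free-energy objective with Gaussian
hyperpriors).  Each component is then scored by Bayesian model
reduction: ΔF = F(reduced model with the component pinned off) −
F(full model), where more negative ΔF is stronger evidence that the
component contributes.

Raw log evidences are calibrated against a shuffle null: the condition
labels of *U* are permuted (identically across subjects), the whole
fit is repeated, and log Bayes factors LBF<sub>k</sub> =
ΔF<sub>shuffled,k</sub> − ΔF<sub>real</sub> are formed.  A component is
called *credible* when the real effect is three times (ln 3 on the
log-evidence scale) more credible than the 80% or 95% strongest effect
of the null.

The package also covers the design side: enumeration of the eight
trial types with their board geometry (ET near/far 13.0/19.9 cm, HT
near/far 2.3/4.6 cm from the printed LED spacings), timed run
generation (40 trials, five per type, 60% go), canonical-HRF design
matrices for the early and late 2 s planning epochs, and
variance-inflation-factor (VIF = var(E)/var(X)) optimisation of trial
order and timing, targeting the study's bound VIF < 1.15.

## Worked example

Generate a small synthetic dataset with planted gaze-centric distance
(ET, weight 2) and target-direction (T, weight 1) encoding on unit
noise, then run the full analysis:

```r
library(vrsa)

ps  <- makeFixture("tiny", seed = 11)      # 4 subjects x 2 runs x 200 voxels
fit <- fitComponents(subjectPatterns(ps, "s01"))
round(hyperparameters(fit), 3)
#> HT_dist ET_dist HE_dist   T_dir   H_dir   E_dir   noise
#>   0.011   1.061   0.106   0.506   0.061   0.085   0.430

nd <- shuffleNull(ps, K = 200, seed = 12)  # label-shuffle null, group level
evidenceReport(nd)[, c("component", "median_lbf", "credible_80", "credible_95")]
#>   component median_lbf credible_80 credible_95
#> 1   HT_dist      -1907       FALSE       FALSE
#> 2   ET_dist      87559        TRUE        TRUE
#> 3   HE_dist      -4220       FALSE       FALSE
#> 4     T_dir      49658        TRUE        TRUE
#> 5     H_dir      -3352       FALSE       FALSE
#> 6     E_dir      -2904       FALSE       FALSE
```

Exactly the two planted components are credible at both levels.  (The
single-subject weights are roughly half the planted values because the
default pooling averages each condition's pattern across the two runs,
which halves every variance component; the shuffle-null calibration is
unaffected.)  `runPipeline(studyConfig(...))` drives the same chain
over several datasets (e.g. ROIs × epochs) and writes TSV/JSON reports
stamped with the config hash and master seed.

On the design side:

```r
opt <- optimizeDesign(nCandidates = 200, seed = 1)
opt$achievedVIF
#> [1] 1.11747
```

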