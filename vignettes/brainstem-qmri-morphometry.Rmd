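---
title: "Methods: synthetic brainstem qMRI morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic brainstem qMRI morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, the parameters
that matter, the numerical choices behind them, and what the synthetic
phantom does and does not establish about real data.

## 1. The forward signal model

All simulation and estimation rest on the steady-state spoiled gradient-echo
(FLASH) equation with a multiplicative magnetisation-transfer saturation
term applied in the dual-excitation approximation:

$$S = A\,\sin\alpha\,(1-\delta)\,
      \frac{1-E_1}{1-\cos\alpha\,(1-\delta)\,E_1}\;e^{-TE\cdot R_2^*},
      \qquad E_1 = e^{-TR\cdot R_1}.$$

`A` is the effective proton-density amplitude (arbitrary signal units),
`R1` the longitudinal relaxation rate (1/s), `R2*` the effective transverse
rate (1/s), and `delta` the fractional MT saturation (reported in percent
units, p.u. = 100·δ). The MT term multiplies both the excitation and the
recursion term, i.e. the saturation pulse acts once per TR like a second,
partial excitation. The three default protocols are T1w 25 ms/23°,
PDw 25 ms/4°, MTw 37 ms/9°, with seven equidistant echoes 2.46–17.22 ms for
all weightings and an additional 19.68 ms echo for PDw and T1w.

Assumptions: perfect spoiling, a single compartment per tissue class, and
Gaussian (not Rician) additive noise. At the signal-to-noise ratio of
averaged echoes the Gaussian approximation to the Rician magnitude
distribution is accurate, and it keeps the estimator calibration tests
interpretable (unbiasedness holds exactly rather than approximately).

## 2. The phantom

`phantomConfig()` / `makePhantom()` generate a brainstem-like template on a
48×64×96 voxel grid at 1 mm (chosen as brainstem scale rather than whole
brain so every test runs in minutes; all geometry is specified in grid
fractions, so smaller grids used in the unit tests are scale models of the
same object). Seven classes emulate compartments of the kind a brainstem
tissue model distinguishes: a white-matter tegmentum matrix, CSF (exterior
plus an aqueduct tube), paired corticospinal-tract columns, a medial
lemniscus column, a periaqueductal-grey annulus in the upper third, and
paired red-nucleus and substantia-nigra ellipsoids. Class boundaries are
softened with a Gaussian kernel (σ = 0.75 voxel) and renormalized, so each
voxel carries a probability vector summing to one — partial-volume voxels
are first-class citizens of the simulation. No claim is made that a class
equals a specific anatomical nucleus; the geometry exists to give the
segmentation and registration problems realistic structure.

Per-subject realization: class parameters are multiplied by mean-preserving
log-normal factors (between-subject CV 0.05); multiplicative bias fields are
exponentiated order-2 polynomials with log-amplitude 0.05 per weighting
(strictly positive by construction); and a random smooth stationary velocity
(Gaussian noise smoothed at σ = 6 voxels, RMS 1 voxel) is exponentiated by
scaling-and-squaring into a subject-specific diffeomorphism. Default noise
sd is 5 signal units on echoes whose tissue signal is roughly 40–95 units;
after 6-echo averaging this corresponds to SNR of order 20–50.

Patients additionally receive a `groupEffect()`: a spherical region
(default 500 voxels in the left corticospinal-tract column at mid-medulla
level) where a contraction velocity `v = (log s / 3)(x − c)·w(x)` encodes a
local volume scaling `s` (default 0.85, i.e. 15% atrophy) and where the
class parameters are blended toward a lesioned set (MTsat −0.4 p.u.,
R1 −0.05 1/s by default) through a smooth window `w`. The window is the
smoothed indicator of a slightly enlarged sphere so that `w ≈ 1` across the
whole region; the Jacobian of the resulting deformation then integrates to
`s` times the region volume to within the interpolation error. Per-patient
severity is drawn from U(0.5, 1.5), and clinical scores follow a truncated
linear link `score = s0 − slope · (realized mean MT reduction) + noise`
(the generating law is a package choice: the underlying study design only
asserts an association between lesion magnitude and impairment, not a
functional form).

What the phantom does *not* emulate: k-space artefacts, parallel-imaging
noise correlations, motion, susceptibility distortion, B1+ transmit-field
maps (bias is a generic smooth field), Rician noise (available as a design
extension), or anatomically faithful nucleus shapes. Tests passing on the
phantom therefore certify the *estimators and their calibration*, not
robustness to acquisition artefacts.

## 3. Relaxometry

`averageEchoes()` averages echoes 1–6 by default: those echoes are common to
all three weightings, so the three means carry one common effective echo
time and the `exp(−TE·R2*)` factor cancels exactly from the parameter
estimators (averaging different echo sets per weighting would bias MT and
R1). `fitR2star()` fits `log S` against TE by ordinary least squares on the
raw PDw echoes — all 8 by default, configurable — and flags voxels with any
non-positive sample. `estimateR1Amplitude()` uses the dual-flip-angle
rational (small-angle) approximation of the FLASH equation; its algebra is
its own exact inverse, and against the exact steady-state equation at the
default protocol the R1 error is ≈1% over R1 ∈ [0.25, 2] (the unit tests
measure this with an independent root-finding oracle). `estimateMTsat()`
computes `δ = (A α/S_MT − 1)·TR·R1 − α²/2`; the approximation error grows
with δ (≈3% relative at 2 p.u., ≈5% at 4 p.u.), which is why the recovery
contract is 2% for R1 but 5% for MTsat. All outputs are scale-equivariant:
scaling every input signal by c leaves MTsat, R1, R2* unchanged and scales
A by c.

`correctBias()` stands in for a full hierarchical transmit-field correction:
it fits a low-order (≤4) 3-D polynomial in the log domain, by ridge
regression against the deviation from within-class medians (classes =
equal-width bins of the log intensities), exponentiates, and gauge-fixes the
field to mean 1 over the mask. Degenerate fits (condition number > 1e10)
fall back to the identity field with a warning.

## 4. Tissue model

The segmentation model is a multivariate Gaussian mixture over image
channels (default MTsat + the PDw echo mean) with spatially varying priors
π_k(v). `eStep()` computes responsibilities with log-sum-exp
stabilization; `mStep()` updates means, covariances and mixing weights;
`updateTPMs()` averages aligned responsibilities across subjects with a
Dirichlet pseudocount (α = 1e-4 per class) so no prior ever hits zero.
`fitEM()` reports the MAP objective (weighted log-likelihood plus the
Dirichlet term); this trace — not the raw observed likelihood, which a
floored prior could make dip by rounding — is the quantity guaranteed
non-decreasing, and the tests assert its monotonicity to 1e-8 relative.
Convergence: relative objective change below 1e-6, at most 200 iterations
(both configurable; values chosen as conventional EM defaults).

Two estimator choices matter on soft-boundary data and are worth spelling
out, because both were driven by a diagnosed failure mode rather than taste:

* **Tied covariance** (`covariance = "tied"`, the segmentation default):
  with per-class covariances, the partial-volume halo around each structure
  inflates the covariance of the broader classes asymmetrically, and the
  broadest Gaussian swallows its neighbours' boundary voxels. A pooled
  covariance makes class boundaries symmetric (nearest-mean in Mahalanobis
  terms), which is the behaviour a human rater would call correct at a
  blurred edge. Per-class covariances remain available for data where the
  classes genuinely differ in spread.
* **Confidence-weighted estimation** (`voxelWeights = priorConfidence(priors)`):
  partial-volume voxels have no single true class, and letting them enter
  the M-step at full weight biases class means toward the blend (the thin
  aqueduct CSF class is the extreme case: most of its prior mass sits on
  blended voxels, so its fitted mean drifts far from pure-CSF values and it
  starts absorbing neighbouring tissue). Weighting each voxel by
  `max(2·max_k π_k(v) − 1, 0)` — a linear ramp from fully ambiguous to pure
  — estimates class parameters from representative tissue while still
  classifying every voxel. Formally this is EM on fractionally replicated
  voxels, so the weighted objective retains the EM monotonicity guarantee.

Initialization is seeded k-means by default and prior-weighted moments
(`init = "priors"`) when informative spatial priors are supplied — the
latter anchors class indices to the prior field, which is what segmentation
against a template requires. Covariance degeneracy is handled by an
eigenvalue floor at 1e-6 of the mean channel variance (with an absolute
floor of 1e-12 so identical data still yield a positive-definite matrix).
Missing voxels are excluded listwise per voxel before fitting.

Evaluation protocol for segmentation accuracy: Dice is computed inside the
analysis mask eroded by 2 voxels (excluding the shell where the "true"
label is itself a coin flip between tissue and exterior CSF) and over
voxels whose ground-truth maximum class probability exceeds 0.7 — where the
phantom's argmax label is actually meaningful. Classes occupying at least
1% of those voxels must reach Dice ≥ 0.90; on the default phantom at noise
sd 2 all seven classes do.

`mergeTPMs()` embeds learned brainstem priors into a whole-volume prior set:
inside the mask the brainstem classes are scaled by one minus the
background mass, the merged field is renormalized, and the largest mass
violation is reported.

## 5. Registration and morphometry

Deformations are parameterized by stationary velocity fields exponentiated
with scaling-and-squaring (6 squarings by default; at the displacement
magnitudes used here the composition error is far below the interpolation
error). This parameterization was chosen over geodesic shooting because it
delivers the same contracts — diffeomorphic mappings, analytic inverses by
negating the velocity, positive Jacobians — at a fraction of the
implementation and run-time cost, and none of the package's claims depend
on the metric structure that shooting adds. Jacobians come from central
differences of the mapping (one-sided at the faces; face voxels are
excluded from morphometric statistics by the mask erosion).

`registerPair()` is a log-demons scheme: the update force is the multi-class
sum-of-squared-differences gradient, smoothed with a "fluid" Gaussian
(σ = 2 voxels), added to the velocity with an adaptive step, and
re-smoothed with an "elastic" Gaussian (σ = 1.2 voxels); steps are accepted
only if the SSD objective decreases, ten consecutive rejections end a
level, and a 3-level multiresolution pyramid (block-mean downsampling)
provides capture range. SSD on class probabilities was preferred over a
multinomial likelihood for robustness and simplicity. The hyper-parameters
are package defaults, not derived from any publication; the tests document
what they achieve: a 2-voxel translation recovered within 25%, and a 10%
regional contraction recovered with mean regional Jacobian inside
[0.85, 0.95] when registering a structure-rich crop at fine resolution.
Volume-change recovery by intensity-driven registration is intrinsically
diluted by regularization — the Jacobian deficit leaks past the region
boundary — which is why the band is one-sided toward 1.

`buildPopulationMean()` alternates register-all-to-mean with voxelwise
averaging and renormalization; velocities are centered across subjects every
round, which keeps the mean log-Jacobian near zero (drift control, |mean| <
0.05). `warpQMap()` performs pullback trilinear resampling with NA outside
the field of view and applies **no smoothing** — the analysis operates on
unsmoothed warped maps, trading sensitivity for spatial specificity, and
the random-field inference accounts for the resulting low smoothness.

## 6. Statistical inference

`fitGLM()` solves the voxel-wise least-squares problem with a single
contrast; t-statistics convert to Z-equivalents by tail-symmetric
probability mapping computed in log space so extreme t-values stay finite.
`estimateSmoothness()` uses the variance of spatial first differences of the
voxel-normalized residuals, solves the Gaussian autocorrelation model
exactly, and adds one voxel² in quadrature as a lattice-sampling
correction — unsmoothed white noise then reports ≈1 voxel FWHM instead of
the ≈1.18 the naive formula gives, and a 3-voxel kernel is recovered within
a few percent.

`clusterInference()` thresholds at the upper-tail t-quantile for the
cluster-defining p (default 0.001), extracts 26-connected components
(26-neighbour connectivity is the common neuroimaging convention; the
choice is exposed nowhere else), and assigns each cluster a family-wise
error corrected p-value from the Gaussian-random-field approximation:
expected cluster count = expected Euler characteristic over the ROI's
lattice resel counts (R0–R3 with the t-field EC densities, Gaussian
densities when df = Inf), extent tail `P(n ≥ k) = exp(−β k^{2/3})` with β
matched to the expected cluster size, and
`p_FWE = 1 − exp(−E[m]·P(n ≥ k))`. The correctness reference for this
chain is Monte-Carlo: on 500 simulated smooth Gaussian null fields
(FWHM 3 voxels, 32³ mask) the empirical family-wise error at nominal 0.05
falls in the 0.02–0.08 calibration band, on the conservative side — the
known behaviour of random-field theory at low smoothness. Peak coordinates
are reported in template-space millimetres about the grid centre; the
template is phantom-defined, so these coordinates are *not* comparable to
any standard brain atlas space.

`runStudy()` applies the same machinery per modality (log-Jacobians for
volume, warped MTsat/R1/R2* for microstructure) with listwise deletion of
subjects missing the effect variable or a covariate (the per-contrast n is
reported alongside each cluster), and by default reports only clusters
significant after FWE correction. Multiple contrasts are *not* corrected
across — mirroring exploratory practice — and a flag exposes all clusters
when needed.

## 7. Clinical layer

`readCohortTable()` ingests and validates the cohort CSV (score bounds,
segment labels, typed missing values); the packaged
`inst/extdata/table1_cohort.csv` is a 30-patient chronic spinal-cord-injury
table whose summaries (`summarizeCohort()`: mean, n−1 standard deviation,
range; time since injury in years) the acceptance tests check at printed
precision. `deriveLevels()` implements the neurological-level rules: the
sensory level is the most caudal dermatome with 2/2 light touch and
pinprick and everything rostral intact; the motor level walks the key
myotomes (≥3/5 with all rostral graded 5) and, across the thoracic
key-muscle gap, follows the sensory level — the standard convention for
segments without a key muscle; the neurological level of injury is the most
rostral of the two. Completeness is AIS grade A. Counting tetraplegia from
tabulated motor/sensory sites is ambiguous for T1-level entries, so
`tetraParaCounts()` surfaces the count under both conventions (cervical
motor site; cervical either site) rather than forcing one.

## 8. Problem sizes and determinism

The test suite runs the expensive checks at sizes chosen so the whole suite
completes in a few minutes on one CPU: the default 48×64×96 phantom for the
segmentation-accuracy and volume-bookkeeping checks, 24×32×48 scale models
for cohort-level properties, 32³–40³ masks with 200–500 Monte-Carlo
replicates for the inference calibrations. All stochastic steps are seeded;
identical seed and configuration reproduce cohorts, pipelines and result
tables bit-identically.

## 9. Known limitations

* The phantom's partial-volume model blends class *signals*, not relaxation
  parameters; at boundary voxels no single true parameter exists, so
  estimator accuracy is certified on pure-tissue voxels.
* The rational dual-flip-angle approximation carries a systematic ~1% R1 and
  ~3–5% MTsat bias at the default protocol; applications needing exactness
  should invert the full steady-state equation numerically.
* Registration-based volume-change recovery is regularization-limited; very
  small or low-contrast lesions will be underestimated (the simulator's
  ground-truth deformations quantify this gap).
* Random-field cluster inference is approximate and conservative at low
  smoothness; a permutation-based alternative would trade run time for
  exactness and is a natural extension.
* The tetraplegia/paraplegia assignment from site labels, and anatomical
  identification of learned classes, are deliberately out of scope.
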