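---
title: "Registration, error models and targeting cues: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration, error models and targeting cues: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgnav)
```

This vignette explains the models behind `surgnav`, the parameters that
matter, the numerical choices, what the synthetic-data generator does
and does not emulate, and the design decisions that were genuinely open.

## Coordinate conventions

All world coordinates are millimetres in a right-handed frame; the CT
world frame is the reference and is fixed to **LPS** orientation (the
DICOM convention). Volumes carry an index-to-world affine with voxel
centers at integer 0-based indices; NIfTI I/O flips the first two affine
rows to and from the RAS convention that format mandates. Rotations are
stored as 3 × 3 matrices internally; tracking streams ship quaternions
`(qw, qx, qy, qz)`, which are normalized on read. Reflections are
rejected everywhere: a registration of anatomy is never a mirror image.

## Paired-point rigid registration

`fit_rigid()` solves the orthogonal Procrustes problem: demean both
point sets, form the cross-covariance `H = Xcᵀ Yc`, take its SVD
`H = U S Vᵀ`, and set `R = V D Uᵀ` with `D = diag(1, 1, det(V Uᵀ))`.
The determinant correction flips the smallest singular vector whenever
the unconstrained optimum would be a reflection, so the returned
rotation is always proper. The translation follows from the centroids.
This closed form is exact: the noiseless construct-and-recover tests
demand residuals below 1e-9 mm.

The **fiducial registration error** is reported as the RMS over
fiducials, `FRE = sqrt(mean(residual_i²))`, not the mean of norms. The
RMS convention is what makes the expectation identity
`⟨FRE²⟩ = (1 − 2/N)⟨FLE²⟩` hold, which the package both uses
(`fle_from_fre()`) and verifies by simulation, so it is adopted as the
single reporting convention.

**Correspondence.** `match_correspondence()` searches ordered
arrangements of one label set against the other exhaustively — at most
8! = 40 320 closed-form fits, each microseconds — and returns the
pairing of minimum FRE. If the runner-up pairing is within
`ambiguity_margin` (default 0.1 mm) of the best, the configuration is
declared ambiguous and an error is raised instead of a silent guess: a
perfectly square marker arrangement, for instance, has four
indistinguishable labelings. The margin default reflects the scale of
registration residuals at sub-millimetre localization noise; it is a
safety device, not a tuning knob.

## Error models

Localization noise is described by the **fiducial localization error**
(FLE), an RMS over all three axes. Independent sources compose in
quadrature (`combine_fle()`); the package default pairing of 0.1 mm
(image-space centroid localization) with 0.7 mm (electromagnetic
tracking) composes to 0.707 mm. Isotropic noise has per-axis variance
FLE²/3; anisotropic noise may be supplied as a full 3 × 3 covariance
whose trace must equal FLE².

**TRE prediction.** `predict_tre()` implements the classical first-order
closed form for the RMS target registration error of a rigid fit on N
fiducials with isotropic FLE:

$$\langle TRE^2(r)\rangle \;=\; \frac{\langle FLE^2\rangle}{N}
\Big(1 + \tfrac13 \sum_{k=1}^{3} \frac{d_k^2}{f_k^2}\Big),$$

where the fiducial configuration is demeaned and rotated into its
principal axes, $f_k$ is the RMS distance of the fiducials from axis
$k$, and $d_k$ is the distance of the target from that axis. The first
term is the translational floor (FLE/√N at the centroid); the sum is the
rotational lever-arm amplification that makes distant targets — a
brainstem target ~70 mm from a nasopharyngeal marker cluster — several
times less accurate than the registration residual suggests.

**Covariance path.** `predict_tre_covariance()` derives the same
quantity by explicit linearization: to first order the displacement at
target $r$ is $d = \bar\varepsilon + \delta\omega \times (r - c)$, with
the small rotation $\delta\omega$ solving the demeaned normal equations
$\big(\sum_i (|x_i|^2 I - x_i x_i^\top)\big)\,\delta\omega = \sum_i x_i
\times \varepsilon_i$. Since $d$ is linear in the per-fiducial noise,
its covariance follows directly; this path accepts anisotropic FLE,
while the closed form requires isotropy and refuses otherwise. For
isotropic noise the covariance trace equals the squared closed-form RMS
to 1e-6 relative — the two derivations cross-validate each other, and
both are validated against the Monte-Carlo oracle.

**Monte-Carlo oracle.** `monte_carlo_tre()` perturbs both sides of the
correspondence with their respective noise, refits the rigid transform,
and records the displacement at the target; the inner loop (closed-form
fit per repetition) is compiled C++ using R's RNG, so 10⁵ repetitions
take ~0.3 s and are exactly reproducible under a seed. The test suite
requires analytic-vs-empirical agreement within 3% at 10⁵ repetitions
across random 4–8 fiducial configurations, the FRE law within 2%, and
the empirical 3 × 3 covariance within 5% Frobenius.

**Confidence ellipses.** For a bivariate normal with covariance Σ the
boundary of the level-p region is the ellipse with semi-axes
$\sqrt{\chi^2_2(p)\,\lambda_i}$ along the eigenvectors of Σ
($\chi^2_2(0.95) = 5.99146$). Coverage is verified empirically to
0.950 ± 0.005. These ellipses are emitted as geometry (semi-axes,
orientation) for drawing around tip and target in the lateral plane —
rendering is out of scope by design.

## Pivot calibration

While the instrument tip rests on a fixed point, every pose satisfies
$R_i t_{tip} + p_i = p_{pivot}$. Stacking all poses gives a 3K × 6
linear system solved in one shot by SVD least squares — the algebraic
variant was chosen over iterative sphere fitting because it is
closed-form, testable, and standard. Rotation diversity is enforced by a
condition-number threshold (10⁶) on the design matrix; pivoting about a
single axis leaves the tip component along that axis unconstrained, and
the error message names the unconstrained direction. No accuracy figure
is assumed for any particular hardware: acceptance is purely
property-based (exact noiseless recovery; < 0.2 mm tip error under
0.2 mm sensor noise with 200 poses over a 60° cone).

## Fiducial detection in CT-like volumes

Titanium is far brighter than tissue, so detection is threshold-first:
Otsu's criterion on a 256-bin histogram of the whole volume (overridable
with an explicit threshold), 26-connected component labelling over the
foreground voxels, filters on component size (≥ 5 voxels) and
equivalent-sphere diameter (2–8 mm around the 4 mm markers), exclusion
of border-touching components, and finally an intensity-weighted
centroid (weights are intensities above threshold) mapped through the
affine to world mm. Sub-voxel accuracy comes from the partial-volume
intensity profile at the sphere boundary; the phantom tests require RMS
centroid error ≤ 0.2 voxel at 0.43 × 0.43 × 0.6 mm spacing, consistent
with ~0.1 mm image-space FLE.

The phantom generator rasterizes spheres with per-voxel overlap
fractions approximated by 3³ supersampling, then adds white Gaussian
noise. It emulates contrast and partial-volume blur; it does **not**
emulate metal artifacts, beam hardening, or anisotropic CT noise
correlation — so passing detection tests demonstrate sub-voxel centroid
behavior under idealized contrast, not robustness to streak artifacts.

**Stability assessment** aligns the postoperative marker set onto the
preoperative one with the best rigid fit before measuring per-marker
residuals; raw coordinate differences would conflate head repositioning
between scans with genuine marker migration. Note a subtlety verified in
the tests: the best fit spreads a single marker's displacement over all
residuals according to leverage, so the displaced marker carries the
maximum residual reliably only when it is not an extreme, high-leverage
vertex of the configuration.

## Targeting cues

The instrument frame has ẑ along the tool axis (tip-forward) and x̂, ŷ
spanning the transverse plane. With Δ = target − tip: depth = Δ·ẑ
(positive ahead of the tip, negative once overreached) and lateral =
(Δ·x̂, Δ·ŷ), so lateral² + depth² = |Δ|² identically. The per-frame cue
state is a pure function of this decomposition:

* in range (lateral norm ≤ `in_range_radius`; ties go in range — a
  deterministic, hysteresis-free boundary): blob offset
  `lateral_scale · lateral` px, circle diameter `depth_scale · |depth|`
  px, circle hidden when |depth| ≤ `zero_tolerance`, blinking iff
  depth < −`zero_tolerance`;
* out of range: no blob, an arrow at `atan2(lateral_y, lateral_x)`, and
  a constant-diameter circle.

`zero_tolerance` defaults to 0.05 mm so that the "cues overlap / circle
vanishes" state is reachable with floating-point streams. Blink is a
boolean flag, not a waveform, and the arrow encodes direction only —
neither a blink frequency nor an arrow-length scale is part of the
contract. Dwell capture stores the earliest window of ≥ 2 s whose
samples all lie within 1 mm of the window mean ("several seconds at a
single location" quantified once as 2 s / 1 mm); the captured position
is the window mean.

## Placement assessment

`placement_error()` splits achieved − planned into a depth component
along the electrode-plane normal and a lateral component within the
plane, alongside the Euclidean norm; the three satisfy the Pythagorean
identity by construction. `summary_stat()` is the mean ± sample standard
deviation (n − 1) used in all accuracy tables, with NA entries (lost
check-points) excluded. `screw_tre()` reduces multiple pointer touches
per screw to the mean touch-to-image distance — the reduction over
repeated touches is not otherwise specified, so the mean is documented
and tested. Report rounding is half-away-from-zero to 2 decimals; raw
doubles are always retained in JSON.

## The synthetic-session generator

`simulate_session()` defines the study conditions: 4 fiducials drawn
uniformly in a 25 mm ball (the nasopharyngeal cluster), target 70 mm
from the cluster centroid, 8 screws at 40–90 mm, 3 touches per screw,
and isotropic localization noise of 0.1 mm RMS (image) and 0.7 mm RMS
(tracker) applied independently to the two spaces, composing in
quadrature. Cluster draws are rejected when they are near-collinear or
when any non-identity labeling of the noiseless markers fits with an FRE
below 3 × (FLE_image + FLE_EMT): automated correspondence is only
well-posed for asymmetric marker arrangements, which is also how
physical marker carriers are designed. Trajectory kinds cover the three
behaviors the display must classify: a straight 10 mm approach at
5 mm/s, a jittered 4 s dwell (σ = 0.2 mm), and an out-of-range lateral
excursion that enters the range once.

What the generator does not emulate: tissue deformation and brainstem
shift (the navigation concept itself does not compensate for them),
electromagnetic field distortion near instruments, correlated or
heteroscedastic tracking noise, and time-varying marker migration.
Passing end-to-end tests therefore demonstrate the *statistical
consistency* of the pipeline under its stated noise model, not clinical
accuracy.

## Numerical choices and degenerate inputs

* Orthonormality, unit-norm and Pythagorean identities are enforced or
  tested at 1e-9; validation tolerances are absolute because all
  quantities are O(1–100) mm.
* Collinearity is detected by the second singular value of the demeaned
  configuration (relative threshold 1e-9); collinear fiducials raise
  degenerate-geometry errors in fitting and TRE prediction (where a
  target off the axis of a collinear configuration has unbounded
  predicted error).
* The principal-axis frame uses `eigen()` on the demeaned scatter;
  eigenvalues are clamped at zero before the fₖ are formed.
* Monte-Carlo problem sizes were chosen so sampling error sits well
  below the asserted tolerances: 10⁵ repetitions give ~0.2% standard
  error on an RMS, against 2–3% tolerances; ellipse coverage uses 10⁵
  draws against a ±0.5% band. The full test suite runs in about a
  minute on one core.
* Report JSON is written with full double precision (`digits = NA`);
  rounding happens only in the human-readable `rounded` blocks.

## Known limitations

* The closed-form TRE model is first-order in FLE/geometry ratio; at
  extreme noise or tiny clusters the Monte-Carlo oracle is the
  authority, and the package treats it as such in its own tests.
* The exhaustive correspondence search is exact but limited to 8
  fiducials per side; larger sets would need the geometric-hashing
  class of algorithms, which this system's 4-marker design does not
  require.
* Detection assumes a single global threshold separates marker material
  from background — adequate for titanium in soft tissue, inadequate
  near dense bone or metal artifacts.
* Cue geometry is emitted as data; no claim is made about perceptual
  adequacy of any particular pixel scaling, which is explicitly a
  surgeon preference.
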