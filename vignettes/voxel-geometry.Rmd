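---
title: "Voxel geometry and the labeling accuracy of small nuclei: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel geometry and the labeling accuracy of small nuclei: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Small subcortical nuclei such as the subthalamic nucleus (STN, ~130 mm^3) and
the internal globus pallidus (GPi, ~380 mm^3) are routinely delineated on MR
images whose voxels are large, and often anisotropic, relative to the
structure. Every voxel that straddles a border mixes the signal of both
sides — the partial volume effect (PVE) — so the apparent border blurs and
the labeled volume and shape drift away from the truth. `voxphantom`
quantifies that drift in isolation: no noise, no contrast physics, no rater
fatigue — only voxel geometry.

The ground truth is an analytic ellipsoid (default semi-axes 2.7 x 2.7 x
5.4 mm, volume 164.9 mm^3, i.e. the size range of DBS targets) placed in a
36 mm cubic field of view. Rather than rasterizing it, the package samples
its exact continuous Fourier transform on the k-space grid conjugate to the
target voxel grid, the same construction as the classical 3D analytic head
phantom. For a unit-intensity ellipsoid with semi-axes $(a,b,c)$, rotation
$R$ and centre $x_0$,

$$F(k) \;=\; 4\pi abc\,\frac{\sin u - u\cos u}{u^{3}}\;
e^{-2\pi i\,k\cdot x_0},
\qquad u = 2\pi \lVert \mathrm{diag}(a,b,c)\,R^{\mathsf T}k \rVert ,$$

with the removable singularity at $k=0$ evaluated by its limit $1/3$, so the
DC sample equals intensity times volume exactly. An inverse DFT then yields
an image whose edge ramps and Gibbs ringing are exactly the PVE a band-limited
MR acquisition of that object would show at that resolution. Because the
object never touches a pixel grid before the final reconstruction, changing
the voxel geometry changes *only* the sampling, never the object.

The 36 mm FoV is chosen so that every design resolution tiles it exactly:
in-plane sizes \{0.1, 0.2, 0.5, 1.0, 2.0\} mm crossed with slice-thickness
factors \{1.0, 1.2, 1.5, 1.8, 2.0, 3.0\} all give integer matrix sizes
(including the odd 15- and 9-slice matrices at 2.0 mm in-plane), so no
interpolation ever enters the pipeline. `grid_spec()` enforces this with a
hard error rather than silently rounding.

## Conventions fixed by this implementation

Several details are genuinely open choices; they are fixed once here and the
tests pin them down.

* **k-space layout.** Frequencies sit at integer multiples of $1/\mathrm{FoV}$
  per axis; `analytic_kspace()` stores them with DC at index
  `floor(N/2) + 1`. `simulate_volume()` produces the identical image while
  emitting samples directly in DFT order (verified bit-for-bit in the tests).
* **Real part, then rescale.** After the inverse DFT the real part is taken —
  the phantom is real, and the small imaginary residue stems only from the
  unpaired Nyquist sample on even grids. Taking the magnitude instead would
  fold Gibbs ringing into positive intensity and bias edge labeling outward.
  Intensities are then min–max rescaled to [0, 1] per volume, which is how a
  rater windows an image; negative ringing therefore maps to small positive
  values. One consequence worth knowing: after rescaling, the background
  plateau sits near 0.07, not at 0; comparisons against the rasterization
  oracle are made on the unscaled reconstruction, where the background is
  genuinely ~0.
* **Geometry conventions.** Euler rotations compose as
  $R_z\,R_y\,R_x$ (degrees); the base orientation (parallel / diagonal /
  orthogonal, i.e. 0deg / 45deg / 90deg of the long axis against the slice
  axis) is applied first, then the random rigid-body transform, both about
  the FoV centre. Voxel centres follow the DFT convention (index
  `floor(N/2)+1` at the FoV centre), and all grids are treated as periodic
  over the FoV — the reconstruction is periodic by construction, and the
  nearest-neighbour upsampling uses the same convention so that integer
  voxel-size ratios preserve mask volume *exactly*, odd matrices included.
  Objects stay at least ~5 mm away from the FoV border under the default
  pose bounds, so periodicity never touches the object.
* **Rigid-body variation.** Uniform per axis within ±4 mm translation and
  ±8 degrees rotation. Each variant's pose seed derives deterministically
  from the master seed and the variant index only, so runs that share a
  master seed share poses (and can share cached reference masks) regardless
  of which design cells they evaluate.

## Raters

The labeling decision is modeled psychometrically: the probability that a
voxel of scaled intensity $i$ is included is
$P = 1/(1 + e^{-(\beta_0 + \beta_1 i)})$. Two probabilistic raters are
shipped: a *liberal* single rater ($\beta_0=-4$, $\beta_1=13$, midpoint
$\approx 0.31$) and a stricter *joint* (two-rater conjunction) rater
($\beta_0=-6.5$, $\beta_1=14$, midpoint $\approx 0.46$). These defaults are
qualitative placeholders — liberal midpoint below joint midpoint, both steep
— because no fitted coefficients are available to ship; every function that
consumes a curve takes it as a parameter, and `fit_psychometric()` re-fits
curves from a user's own (intensity, label) tables by logistic maximum
likelihood, with per-resolution fits pooled by `average_curves()`. Perfectly
separated data (a hard threshold rater) have no finite MLE; the fit is then
flagged and its slope capped at a documented value instead of diverging.

The curve is applied to *all* voxels, not an explicit edge set: the logistic
tails include interior voxels ($i \approx 1$) and exclude background
($i \approx 0$) automatically. Labeling is stochastic by default (independent
Bernoulli per voxel, seeded); an `expected` mode (include iff $P \ge 0.5$)
provides a deterministic surface for regression tests. One behaviour to be
aware of with stochastic labeling: the background tail probability, however
small, multiplies the enormous number of background voxels on fine grids
(a 0.5 mm grid has ~373k voxels, ~0.4% of which the default joint curve
admits), so stochastic probabilistic raters overestimate strongly at fine
resolutions unless their slope is steep enough to push the background tail
below ~1/N. Fitted human curves are typically much steeper than the shipped
placeholders; `expected` mode sidesteps the effect entirely.

The *optimal* rater has no curve. It computes the proportion of the FoV cube
the true ellipsoid occupies ($164.9/36^3 \approx 0.0035$), then thresholds
the image at the intensity whose suprathreshold proportion matches it,
interpolating linearly on the empirical survival function *between distinct
intensity values* (this matters when intensities tie: the threshold then
falls strictly between the tied levels). Two volumes are recorded: the
discrete mask volume (voxel count x voxel volume — what Dice uses), and the
proportion-matched continuous volume implied by the interpolated survival
function. The continuous volume equals the ground truth up to floating
point in every cell — which is why the optimal rater's volume-deviation row
is essentially zero at *every* resolution even though its coarse-grid masks
are blocky; a discrete voxel count at 2 mm voxels could never deviate by
less than ~5%.

## Scoring

Volume accuracy is the signed percentage deviation from 164.9 mm^3. Shape
accuracy is the Dice coefficient score (DCS) against a reference mask: the
optimal rater's labeling of *the same variant* reconstructed at 0.1 mm
isotropic. Trial masks are brought to the reference grid by nearest-neighbour
upsampling (no smoothing, preserving the blocky low-resolution shape). The
per-axis size ratios are integers for every cell of the default design
except the 0.2 mm and 0.5 mm grids at factors 1.2/1.8 (and 1.5 at 0.5 mm),
where the mapping is still exact nearest-neighbour but voxel counts per
source voxel alternate; volume is preserved exactly at integer ratios and to
a fraction of a percent otherwise. An analytic membership mask is also
available (`rasterize_oracle()`), but the reference deliberately uses the
reconstructed 0.1 mm volume: the comparison is then "what this rater saw at
this resolution" vs "what the best rater sees at the best resolution",
holding the imaging physics fixed.

The `rasterize_oracle()` itself is the package's independent ground truth
for testing: brute-force sub-voxel sampling of the analytic ellipsoid,
converging to the exact partial volume. The test suite requires the Fourier
reconstruction and the oracle to agree to a mean absolute difference below
0.02 at 0.1 mm, with agreement degrading monotonically as voxels coarsen.

## The experiment driver and problem sizes

`run_design()` iterates variants (outer), orientations, then resolution
cells, building each variant's reference once and caching it (bit-packed;
a 360^3 mask costs ~6 MB). Everything derives from one master seed and is
bit-reproducible, including the stochastic raters. The full study design —
100 variants x 3 orientations x 30 resolutions — is a long run; the
package's own tests and the bundled acceptance script use reduced cohorts
of 3–5 variants per orientation with all six thickness factors at the
resolutions that carry the conclusions (0.2 mm and 2.0 mm in-plane),
which reproduce the study's qualitative surface: optimal-rater DCS > 0.9
everywhere at 0.2 mm in-plane, collapsing below 0.7 at 2.0 mm with 6 mm
slices. Cell means at these cohort sizes are stable to within a few
hundredths of DCS because the optimal rater is deterministic given the pose.

`same_volume_comparison()` runs the shape-only contrast: 8-fold anisotropic
voxels vs isotropic voxels of identical volume (0.1 x 0.1 x 0.8 vs 0.2^3;
0.5 x 0.5 x 4.0 vs 1.0^3), isolating voxel shape from voxel size.

`fit_dcs_deviation_curve()` summarises how shape error tracks volume error:
a least-squares fit of $\mathrm{DCS} = (1-c)e^{-k\,|dev|} + c$, anchored at
(0, 1) by construction, with the analytic inverse
`deviation_at_dcs()` translating DCS guideline levels (0.90 "ideal",
0.75 "acceptable") into tolerable volume deviations. The exponential form
is a modeling choice — it is monotone, anchored, and has an interpretable
floor $c$ — and the guideline thresholds reported by the package come from
its own fit, not from any published coefficients.

## Numerical choices and degenerate inputs

* Matrix dimensions must match `fov / voxel` to 1e-6 or `grid_spec()` errors.
* The $u \to 0$ envelope limit switches to a second-order Taylor expansion
  below $u = 10^{-4}$.
* The survival-function threshold search uses an exact algorithm; on large
  volumes a 65536-bin histogram brackets the crossing and only a small
  value range is sorted, widening adaptively (and falling back to a full
  sort) when ties straddle the bracket — results are identical either way.
* Constant images make the optimal threshold undefined: hard error.
* Exact half-voxel boundary points in upsampling go to the higher index,
  with a 1e-6 index tolerance so that exactly-rational size ratios are not
  broken by floating-point rounding of voxel coordinates.
* Empty-vs-empty masks score Dice 1 by convention.
* A 0.1 mm reference reconstruction holds a 360^3 complex array (~750 MB)
  transiently; peak memory of a reference build is ~2.5 GB.

## What the generator does and does not emulate

The phantom reproduces exactly one mechanism: band-limited sampling of a
sharp-edged object at a chosen voxel geometry, i.e. the pure PVE. It does
not model MR noise, coil sensitivity, relaxation contrast, susceptibility,
motion during acquisition, or irregular anatomical shape — all deliberately
excluded so that voxel geometry is the only manipulated variable. Passing
tests therefore demonstrate the geometric floor of labeling error: real
acquisitions can only do worse. Extrapolation to a specific nucleus should
respect that its shape, contrast and neighbourhood differ from an ideal
ellipsoid.

## Known limitations

* The liberal/joint psychometric coefficients are placeholders; any result
  that depends on them (e.g. absolute overestimation percentages of the
  probabilistic raters) is parameter-dependent and should be re-derived
  from curves fitted to one's own raters. The package's quantitative
  claims are made with the parameter-free optimal rater.
* Dice against the 0.1 mm reference is itself quantized at the coarsest
  grids; a 2 mm-in-plane mask contains few voxels and single-voxel
  inclusion flips move a cell's DCS visibly. Cohort means smooth this but
  small-cohort cell means at 2.0 mm carry a few hundredths of spread.
* The periodic-grid convention wraps content at the FoV border; it is
  invisible under the default pose bounds but matters if objects are
  pushed within a voxel of the border.
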