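---
title: "Synthetic MPRAGE morphometry: models, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic MPRAGE morphometry: models, phantom and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphosynth)
```

## The problem

Morphometry pipelines (voxel-based morphometry, surface-based cortical
thickness) estimate anatomy from T1-weighted images, but T1-weighted
intensity mixes three microstructural parameters: the longitudinal
relaxation rate R1 (largely myelin), proton density PD (tissue water)
and the effective transverse rate R2* (iron). A change in any of them
changes gray-white contrast and therefore where segmentation places
tissue boundaries — producing apparent volume or thickness changes
without anatomical change. `morphosynth` makes this mechanism
quantitative on a controlled digital phantom: it synthesizes MPRAGE
images from quantitative maps with each parameter's contribution
individually removable, and measures how contrast, apparent GM volume
and slab thickness respond.

## Signal models

### FLASH (mapping acquisitions)

The forward model of the mapping acquisitions is the spoiled
gradient-echo steady state (Ernst equation)

$$S = \mathrm{PD}\,\sin\alpha_\mathrm{eff}\,
\frac{1 - e^{-TR \cdot R_1}}{1 - \cos\alpha_\mathrm{eff}\, e^{-TR \cdot R_1}}
\, e^{-TE \cdot R_2^*},
\qquad \alpha_\mathrm{eff} = \alpha_\mathrm{nom} \cdot b_1,$$

with the dual-flip-angle protocol TR = 24.5 ms, α = 6°/21°, and eight
equidistant echoes from 2.34 to 18.72 ms. All relaxation arithmetic is
done internally in 1/ms (matching the protocol's ms units) and exposed
in 1/s; the factor of 1000 is asserted in the tests.

**R2\*** is estimated by ordinary least squares on
$\ln S(TE) = \ln S_0 - TE \cdot R_2^*$ over the PD-weighted echoes
only; negative fitted rates are clipped to zero (air/noise voxels) and
counted, and voxels with non-positive signal at any echo are set to
`NaN` and counted.

**R1 and PD** come from the exact two-point inversion of the Ernst
equation: with $y = S/\sin\alpha_\mathrm{eff}$ and
$x = S/\tan\alpha_\mathrm{eff}$ the steady state is linear,
$y = E_1 x + \mathrm{PD}(1 - E_1)$, so two flip angles determine
$E_1 = e^{-TR \cdot R_1}$ from the slope and PD from the intercept. We
deliberately use the exact inversion rather than a small-angle rational
approximation: exactness makes the noise-free round trip a machine-
precision test of the whole chain, and the approximation's bias would
otherwise be entangled with implementation error. A slope outside
(0, 1) has no physical $E_1$; such voxels become `NaN` and are counted.

Because the minimal-TE images still carry the factor
$e^{-TE_1 R_2^*}$, `estimate_maps()` first divides the two first-echo
images by that factor using the *fitted* R2* map (option
`correct_r2star_decay`, on by default). This makes noise-free recovery
exact for all three parameters — the round-trip invariant the test
suite enforces at 1e-8 relative error. Disabling it reproduces the
small residual R2* weighting a minimal-TE analysis would carry.

### MPRAGE (synthetic T1-weighted images)

One MPRAGE cycle is: adiabatic inversion, free recovery, a train of
`n_lines` excitations of angle α at echo spacing ES (duration
τ = n_lines × ES), and a recovery delay TD until the next inversion.
During the train the longitudinal magnetization relaxes with the
apparent time constant $1/T_1^* = R_1 - \ln(\cos\alpha)/ES$ towards
$M_0^* = M_0\, T_1^* R_1$. Solving the cycle's affine fixed point and
reading the signal at the train center gives the R1-driven factor

$$f_{R_1} = E_4\,\frac{1 - 2E_1 + E_1E_2}{1 + E_1E_2E_3}
 + T_1^* R_1\,\frac{1 + E_1E_2E_3 - E_4 - E_4E_1E_2}{1 + E_1E_2E_3}$$

with $E_1 = e^{-TI_\mathrm{pre} R_1}$, $E_2 = e^{-TD\,R_1}$,
$E_3 = e^{-\tau/T_1^*}$, $E_4 = e^{-\tau/(2T_1^*)}$. The full signal is

$$S = \sin\alpha \cdot f_{R_1} \cdot f_\mathrm{PD} \cdot f_{R_2^*},
\qquad f_\mathrm{PD} = \mathrm{PD},
\qquad f_{R_2^*} = e^{-TE \cdot R_2^*},$$

and an image type excludes a parameter by setting its factor to
exactly 1 — `synthesize()` implements that rule literally, so the four
image types factor multiplicatively to machine precision.

Two transcription safeguards are built in. First,
`mprage_bloch_reference()` simulates the cycle pulse by pulse (discrete
$\cos\alpha$ rotations, exact inter-pulse recovery, fixed point of the
one-cycle affine map) and shares no code with the closed form; the two
agree within 1% over R1 ∈ [0.2, 2] s⁻¹ at the default protocol, the
residual being the closed form's continuous-relaxation approximation.
Second, the scalar anchors (e.g. T1* = 444.2 ms at R1 = 1 s⁻¹, α = 9°,
ES = 9.9 ms) are frozen from independent evaluation.

**Timing convention.** The default protocol (α = 9°, ES = 9.9 ms,
TI = 960 ms, τ = 176 × ES = 1742.4 ms, TR = 2420 ms) is internally
inconsistent if TI is read as inversion-to-train-start: it would give
TD = 2420 − 960 − 1742.4 < 0. We therefore default to TI measured to
the *center* of the readout (pre-train recovery TI − τ/2 = 88.8 ms,
TD = TR − TI − τ/2 = 588.8 ms), which is the only reading that yields a
physical sequence with these values; the start convention remains
selectable (`ti_convention = "start"`). The synthetic echo time is not
fixed by the protocol above; we default to TE = 3 ms, a typical short
MPRAGE echo time, and expose it as a parameter — R2* effects scale
directly with it.

## Contrast analysis

Gray-white contrast is $C = (WM - GM)/((WM + GM)/2)$, sampled on the
phantom's planar boundary: WM 1 mm subjacent to the border along the
slab normal, GM at 35% of the local cortical thickness. On a voxelized
slab the depths map to indices by round-half-up with a minimum of one
voxel (e.g. 35% of a 10-voxel cortex → the 4th voxel), nearest-voxel
without interpolation; base R's round-half-even would sample
inconsistently across thicknesses.

The contrast change caused by including PD follows in closed form from
the signal and contrast equations. Writing $R = I_{GM}/I_{WM}$ for the
R1-only image and $R_{PD} = PD_{GM}/PD_{WM}$:

$$\Delta C = C(\{R_1\}) - C(\{R_1,PD\})
= \frac{4R\,(R_{PD} - 1)}{(1 + R)(1 + R_{PD}R)} .$$

This "derived" form equals the brute-force difference of sampled
contrasts to machine precision (an exact algebraic identity, enforced
at 1e-12 in the tests), and its sign equals $\mathrm{sign}(R_{PD}-1)$
everywhere — the mechanism by which water-content differences move
boundaries. A second, "printed" variant with denominator
$(1+R_{PD})(1+R)$ circulates in the literature; it agrees in sign and
at the $R_{PD}=1$ zero but differs numerically (0.1497 vs 0.1790 at
$R_{PD}=1.2$, $R=0.7$). Both ship; the derived form is the default and
neither is silently "corrected" into the other.

Thickness change is regressed on contrast change site-wise through the
origin ($\Delta C_t = \beta\,\Delta C + \varepsilon$), with
$t = \hat\beta/\mathrm{SE}$; an optional 1D Gaussian pre-smoothing
along the site ordering stands in for surface smoothing and is off by
default (phantom sites are not a cortical mesh).

## The phantom and cohort

The phantom is a 64³ voxel, 1 mm isotropic slab geometry: WM core,
8-voxel cortical GM slab with a planar GM/WM border normal to z, a
sensorimotor-like half of the slab (high R1, PD ratio to WM closer
to 1), two spherical iron-rich nuclei (radius 5) inside the WM, CSF
elsewhere, and a brain mask (tissue plus a 2-voxel CSF rim). Default
tissue values are order-of-magnitude 3 T literature values chosen to
produce the contrast regimes under study (WM R1 = 1.05 s⁻¹, PD = 0.69,
R2* = 21 s⁻¹; cortical GM 0.72 / 0.83 / 16; sensorimotor-like GM
0.85 / 0.78 / 21; nucleus 0.95 / 0.75 / 45; CSF 0.24 / 1.00 / 1); they
are configuration, not fitted quantities. Noise is additive Gaussian
on magnitude signals — adequate at the simulated SNR but a documented
simplification (no Rician floor). B1 bias fields are smooth low-order
cosine surfaces spanning `1 ± amplitude`.

The simulated cohort mirrors a healthy-ageing study: 120 subjects by
default, ages uniform on 18–78, balanced sexes, and per-tissue
parameter trends `base × (1 + slope·age_c + quad·age_c² + subject
effect)` with a 2% relative between-subject standard deviation —
roughly the inter-individual spread reported for relaxometry
parameters. The ground-truth slopes are stored so recovery is
testable. The interaction analyses use the full 120-subject size;
unit tests use 32³ phantoms and cohorts of 5-40 subjects so the whole
suite runs in minutes.

## Morphometry proxy

The production VBM/FreeSurfer pipelines depend on atlas priors,
diffeomorphic registration and surface reconstruction that are out of
scope here; the proxy isolates the *intensity* mechanism those
pipelines share. It smooths the image with a small Gaussian (default
FWHM 2 mm — the point-spread scale of a 1 mm acquisition), optionally
adds acquisition noise, fits a 3-component Gaussian mixture to the
masked intensities by EM, labels voxels by maximum posterior, and
assigns components to CSF/GM/WM by mean intensity order (T1w polarity).
We explicitly do *not* apply the 6 mm VBM kernel to the intensities:
that kernel belongs to the post-segmentation probability maps, and at
slab scale a σ = 2.5 mm intensity blur degenerates the mixture (the
GM mode merges with the partial-volume ramps), which is a property of
the proxy, not of the mechanism under study.

EM details: deterministic quantile initialization; log-likelihood
recorded every iteration (non-decreasing, asserted); convergence when
the per-observation log-likelihood change drops below 1e-9; a
near-empty collapsing component is re-seeded (logged), while a heavy
component with zero within-component variance — the normal situation
on noiseless piecewise-constant images — is clamped at a small floor
and kept, so clean phantoms are classified exactly. For speed the
mixture is fitted on a deterministic stride of at most 40,000 masked
voxels and then applied to all voxels; at the phantom's intensity
separations the fitted parameters are indistinguishable from the
full fit.

Apparent volumes are label counts × voxel volume (exhaustive over the
mask, so GM+WM+CSF equals the masked volume identically). Slab
thickness per boundary site is the length of the contiguous
classified-GM run along the normal, where the run is anchored to the
*apparent* GM/WM boundary: it extends downward across the nominal
border when classification absorbs WM-side ramp voxels into GM
(apparently thicker cortex) and starts higher when boundary voxels are
absorbed into WM (thinner). This matters: the modality-dependent
boundary shift is precisely the effect under study, and a metric
pinned to the nominal border plane cannot see it.

## Statistics

The group model is ordinary least squares per site with modality
indicator columns, mean-centred age, the square of centred age (itself
re-centred; centring before squaring keeps the linear and quadratic
regressors near-orthogonal), sex, optional subject indicators
(subject-mean removal for paired modality contrasts — with subject
blocks, modality uses treatment coding to keep full rank), and
modality × centred-age interactions. Contrasts give one-tailed t tests
(direction supplied by the contrast sign); zero residual variance is
reported as an infinite-t sentinel with a flag rather than NaN.
Multiplicity is handled by Bonferroni — conservative and exactly
testable, unlike random-field-theory corrections, which are undefined
on this non-stationary phantom. Designs are checked for rank and the
collinear columns are named in the error. The flexible-factorial
covariance structure of the original design (variance/dependence
flags) is approximated by the paired subject-blocking above; this is a
stated simplification, not an inference about the original intent.

The cohort analysis regresses apparent GM volume on this design for
the `{R1}` vs `{R1,PD}` pair. An injected PD ageing trend (GM PD
rising 0.2%/year relative — the generous end of reported water-content
changes) produces a negative modality × age interaction: the
PD-including images lose apparent GM faster with age. A trend-free
cohort shows no interaction. The acceptance test asserts both at a
fixed seed with a 0.01 significance threshold — strict enough that the
trend-free arm's false-positive risk is negligible while the injected
trend at the 120-subject size remains clearly detectable.

## Numerical and degenerate-input conventions

* Non-positive R1 in the signal equation, non-positive signals in the
  log fit, and non-physical two-point slopes yield `NaN` plus QC
  counts, never silent zeros; `estimate_maps()` intersects the three
  parameter masks so the returned mask is honest.
* Synthetic images propagate `NaN` from the maps; the morphometry
  proxy treats non-finite voxels as air (zero) and counts them.
* All randomness flows from explicit integer seeds; pipeline stages
  derive distinct child seeds deterministically, and `run_all()` reruns
  are bit-identical (MD5 checksums in the manifest).
* Gaussian smoothing uses replicated-edge padding; FWHM converts to σ
  by $\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$.

## What the phantom does and does not show

Passing tests demonstrate the *mechanism*: microstructural parameter
differences change contrast exactly as the closed forms predict, and
intensity-driven segmentation converts those contrast changes into
apparent volume and thickness differences with the expected directions
(less apparent GM and thinner cortex when PD is included where
$R_{PD} > 1$; more apparent nucleus GM when R2* is included; a
modality × age interaction only when a PD trend is injected). The
phantom does not emulate cortical folding, atlas priors, registration,
Jacobian modulation, surface placement, Rician noise, or real tissue
heterogeneity, so effect *sizes* here are not predictions for any real
pipeline — only the directions and the algebraic identities transfer.
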