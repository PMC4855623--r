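# morphosynth

Microstructure-driven, apparently "morphological" brain changes:
quantifying how tissue properties leak into T1-weighted morphometry.

Voxel-based morphometry and cortical-thickness pipelines read anatomy
off T1-weighted (MPRAGE) images, but MPRAGE intensity is not a pure
anatomical signal: it mixes the longitudinal relaxation rate R1 (a
myelin correlate), proton density PD (tissue water), and R2* (iron).
When any of these microstructural parameters changes — with age, or
disease — the image contrast changes, tissue boundaries shift, and
segmentation-based volume and thickness estimates change *without any
true anatomical change*.

`morphosynth` implements the full analysis chain needed to demonstrate
and quantify this confound on a digital brain phantom:

1. **Quantitative mapping** — R1, PD and R2* estimation from simulated
   dual-flip-angle multi-echo FLASH acquisitions (log-linear R2* fit
   over the PD-weighted echoes; exact two-point inversion of the Ernst
   equation `S = PD sin a (1-E1)/(1-cos a E1)`, `E1 = exp(-TR*R1)`,
   with B1 transmit-field correction).
2. **Synthetic MPRAGE images** — the closed-form MPRAGE steady-state
   signal

   `S = PD * sin(a) * exp(-TE*R2*) * f_R1(R1; TI, ES, tau, TD)`

   with each factor individually removable, producing the four image
   types T1w(R1), T1w(R1,PD), T1w(R1,R2*), T1w(R1,PD,R2*). A discrete
   Bloch-train simulator ships as an independent validation oracle.
3. **Contrast analysis** — gray-white contrast
   `C = (WM - GM)/((WM + GM)/2)` sampled at the phantom's GM/WM
   boundary (WM 1 mm subjacent, GM at 35% cortical depth), closed-form
   predictions of the contrast change between image types from the
   GM/WM ratios of PD and T1w(R1), and a no-intercept regression of
   thickness change on contrast change.
4. **Morphometry proxy** — Gaussian-mixture (EM) tissue segmentation,
   apparent GM/WM/CSF volumes, and slab cortical thickness.
5. **Statistics** — mass-univariate OLS with modality indicators,
   mean-centred linear and quadratic age, sex, subject blocking,
   modality x age interactions; one-tailed t tests and Bonferroni
   correction.
6. **Phantom & cohort** — a labeled slab phantom (WM core, cortical and
   sensorimotor-like GM, iron-rich deep nuclei, CSF) with per-tissue
   parameters, simulated acquisitions, smooth B1 fields, and a
   seeded multi-subject ageing cohort with configurable parameter
   trends.

## Worked example

```r
library(morphosynth)

ph   <- build_phantom(phantom_geometry())       # 64^3 labeled phantom
prot <- mprage_protocol()                       # a=9deg ES=9.9 TI=960 TR=2420
imgs <- synthesize_set(ph$maps, prot)           # the four image types

a <- sample_boundary(imgs$r1,   ph$labels, ph$geometry)
b <- sample_boundary(imgs$r1pd, ph$labels, ph$geometry)
r_t1 <- a$gm_int / a$wm_int
r_pd <- (b$gm_int / b$wm_int) / r_t1
head(data.frame(measured  = a$contrast - b$contrast,
                predicted = predict_contrast_change(r_pd, r_t1)), 3)
#>   measured predicted
#> 1 0.121819  0.121819
#> 2 0.121819  0.121819
#> 3 0.121819  0.121819

mask <- phantom_brain_mask(ph$geometry)
va <- classify_and_measure(imgs$r1,   mask, noise_sigma = 0.01, seed = 1)
vb <- classify_and_measure(imgs$r1pd, mask, noise_sigma = 0.01, seed = 1)
va$volumes_mm3["gm"] - vb$volumes_mm3["gm"]
#>   gm
#> 1609
```

Including PD in the signal equation lowers GM-WM contrast wherever the
GM/WM proton-density ratio exceeds 1, and the segmentation sees ~1,600
mm³ less apparent gray matter from the same anatomy — the confound the
package is built to expose. The measured contrast change matches the
closed-form prediction to machine precision because the prediction is
the exact algebraic consequence of the signal and contrast equations.

The full pipeline (phantom → acquisition → maps → synthesis → contrast
→ morphometry, with every artifact and checksum written to disk) runs
from one configuration:

```r
run_all(run_config(seed = 1), "out/")
```

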