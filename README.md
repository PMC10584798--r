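# luquant

Quantitative Lu-177 SPECT characterization, entirely in silico: digital
phantoms, an attenuated projector with collimator response, septal
penetration and dual-energy-window (DEW) scatter emulation, in-house OSEM
and BSREM reconstruction with a relative difference prior (RDP), and the
full phantom-analysis stack used to qualify a reconstruction protocol for
dosimetry after Lu-177 radiopharmaceutical therapy.

It is aimed at medical-physics researchers who want a reproducible,
hardware-free testbed for the questions a console characterization answers:
how do the calibration factor, quantification error, noise and recovery
coefficients depend on the algorithm, the number of iterations and subsets,
and the regularization strength?

## The quantities at the core

* **Image calibration factor** (cps/MBq), from a uniform calibration
  cylinder:

  `ICF = C / (T_acq * A_prep * exp(-ln 2 * dt / T_half))`

  with `C` the reconstructed counts in a large VOI around the phantom, and
  relative uncertainty `sqrt((sqrt(C)/C)^2 + u(A)^2)`.
* **Quantification error** `(A_meas - A_true) / A_true`, with
  `A_meas = C_VOI / (T_acq * ICF)`, for an enlarged outer VOI (activity)
  and an interior VOI (concentration) on a second uniform cylinder.
* **Noise** as the coefficient of variation (sd/mean) in the interior VOI.
* **Spatial resolution** by matched filter: the effective Gaussian FWHM
  whose blur of the known digital phantom best matches the reconstruction.
* **Recovery coefficients** `RC = c_meas / c_true * 100 %` for the six
  NEMA IEC spheres (10-37 mm), after trilinear resampling to the CT grid.
* **Clinical stage**: noise-matched protocol selection, peak-1-mL /
  30 %-isocontour lesion segmentation, and exact Wilcoxon matched-pairs
  signed-rank comparisons of lesion concentrations across protocols.

OSEM is the classic ordered-subsets EM with an additive DEW scatter term;
BSREM is relaxed block-sequential ascent on the RDP-penalized Poisson
likelihood (one-step-late preconditioning; algebraically identical to OSEM
at `beta = 0`).  The emulated factory protocol is BSREM 20i10s with RDP
(`gamma = 1`, `beta = 0.08`) and sensitivity-weighted beta.

See `vignettes/luquant-methods.Rmd` for the forward model, the penetration
/ DEW shape-mismatch mechanism behind the interior bias, and all numerical
conventions.

## A worked example

```r
library(luquant)

cfg <- desk_profile(seed = 1)        # 64^3 grid at 4.92 mm, 60 views
rep <- run_characterization(cfg, stages = "quantification")

head(rep$icf[, c("protocol", "icf_cps_mbq", "u_icf_rel")], 3)
#>          protocol icf_cps_mbq  u_icf_rel
#> 1      OSEM 12i1s    94.12253 0.02000061
#> 2 BSREM-RDP 12i1s    92.85704 0.02000062
#> 3      OSEM 48i1s    94.43057 0.02000061

subset(rep$quantification, updates %in% c(96, 192),
       c(protocol, error_outside_pct, error_inside_pct))
#>            protocol error_outside_pct error_inside_pct
#> 5        OSEM 96i1s        -0.4298354        -5.427666
#> 6   BSREM-RDP 96i1s        -0.4049103        -4.600894
#> 7       OSEM 192i1s        -0.4230088        -5.402496
#> 8  BSREM-RDP 192i1s        -0.3970768        -4.624266
```

Reading this output: every protocol's calibration factor lands in the
mid-90s cps/MBq with a 2 % uncertainty dominated by the activity
measurement; the activity in the enlarged outer VOI is accurate to well
under 1 % for every protocol; and the interior concentration is
systematically underestimated by about 5 % at convergence — the septal
penetration effect: correcting the broad penetration tail with the scatter
window's narrower shape over-subtracts under the body core, a deficit the
whole-phantom calibration VOI averages away but an interior VOI exposes.
`rep$noise` shows the noise build-up with OSEM updates (CV 0.06 at 12
updates to 0.51 at 576) and the much flatter BSREM-RDP curve, the
trade-off that protocol optimization by noise matching
(`match_noise()`) navigates.  Adding `"quality"` and `"recovery"` to
`stages` appends matched-filter resolutions and the cold/hot-background
recovery-coefficient tables.

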