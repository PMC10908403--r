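# pwva — noninvasive pulse-wave indices of vascular aging

`pwva` ("pulse-wave vascular aging") is an R package for assessing how well noninvasive pulse-wave (PW)
indices measure aortic stiffness. It computes the nineteen indices most
widely used to track the arterial-stiffening component of vascular aging —
six transit-time pulse wave velocities, blood-pressure morphology indices,
wave-separation quantities, the cardio-ankle vascular index, carotid
distensibility and five photoplethysmogram (PPG) indices — from multi-site
single-beat pressure, flow-velocity, luminal-area and PPG waveforms, and
compares each against an **exact reference aortic stiffness** available for
virtual (simulated) subjects. It is aimed at researchers who evaluate
candidate vascular-aging biomarkers on in silico hemodynamic data before
taking them to the clinic or to wearable devices.

## The quantities at the core

For a virtual subject the wall stiffness of every arterial segment follows
the Olufsen wall law, which ties the stiffness–thickness product to the
luminal radius `r`:

    Eh / r = k1 · exp(k2 · r) + k3

with `h/r = 0.15`. The reference aortic stiffness is the length-weighted
Young's modulus over the 10 aortic segments,

    E_Ao = Σ_j (L_j / L_Ao) · E_j ,    L_Ao = Σ_j L_j ,

and the theoretical aortic-root pulse wave velocity is the thin-wall
elastic wave speed

    aoPWV_t = sqrt( 2 E h / (3 ρ r) ) ,   ρ = 1060 kg/m³.

Measured indices are computed the way they are acquired in practice:
transit-time PWVs use the foot-to-foot method with the intersecting-tangent
foot; augmentation uses the P1/P2 systolic landmarks; wave separation uses
`c = (1/ρ)·sqrt(ΣdP²/ΣdU²)`, `Pf = ½Σ(dP + ρc dU)`, `Pb = ½Σ(dP − ρc dU)`;
CAVI is `c1·ln(SBP/DBP)·(2ρ/PP)·haPWV² + c2`; carotid distensibility is
`(ΔA/A_dia)/PP`; the PPG indices (RI, SI, AGI, AIx, d/a) come from the
systolic/diastolic peaks and the second-derivative a–e waves.

The statistical harness mirrors how such indices are validated: Spearman and
Pearson correlation against `E_Ao` (with young/elderly subgroups),
Bland–Altman agreement of each PWV against `aoPWV_t`, a relative sensitivity
index quantifying confounding by cardiac and vascular properties, and a
noise-robustness experiment that injects white Gaussian noise at prescribed
SNR (15/20/30 dB), band-pass filters (0.0665–35 Hz, zero phase) and
recomputes everything.

Because the deposited virtual-population dataset may not be available
offline, the package ships a **synthetic virtual-subject generator**
(`make_population()`) with known ground truth — stiffness, transit delays,
forward/backward waves, true distensibility — so the entire pipeline is
testable end to end.

## Worked example

```r
library(pwva)

spec <- synthetic_spec(n_subjects = 60, seed = 7)
pop  <- make_population(spec)
pop
#> <synthetic_population> 60 subjects, ages 25-75 yr, E_Ao 4.3e+05-1.4e+06 Pa

ms  <- make_subject(spec, age = 65, id = "demo")
ms$truth
#> <ground_truth> E_Ao=1.07e+06 Pa, aoPWVt=10.03 m/s, DC=7.17e-06 1/Pa

compute_panel(ms$subject)
#> <index_panel>
#>         aoPWV         cfPWV         baPWV         cbPWV         crPWV
#>  9.891186e+00  1.014276e+01  1.068301e+01  1.118305e+01  1.131511e+01
#>         ftPWV           cPP           bPP            AP           AIx
#>  9.963557e+00  1.037668e+04  1.068482e+04  9.341919e+02  9.002800e-02
#>        Pb_amp            RM          CAVI            DC        RI_ppg
#>  3.632001e+03  3.888077e-01  1.748672e+01  6.959718e-06  1.299746e+00
#>        SI_ppg           AGI       AIx_ppg      d_over_a
#>  1.535088e+01 -1.023776e+00  1.098378e+00 -3.888359e-01
```

The 65-year-old subject has a stiff aorta (`E_Ao` ≈ 1.07 MPa): all six PWVs
sit near the theoretical 10.0 m/s, augmentation is positive (the reflected
wave arrives in systole), and the distensibility (7.0 × 10⁻⁶ 1/Pa) is close
to the subject's true value of 1/(ρc²). Pressures are in Pa (cPP ≈ 10.4 kPa
≈ 78 mmHg).

```r
res <- run_full_assessment(pop, spec = spec, snr_levels = NULL,
                           sensitivity = FALSE)
res
#> <va_assessment> 60 subjects
#>
#> Top correlations with E_Ao (all subjects):
#>  index        r_s        r_p  n
#>     DC -0.9997777 -0.9569452 60
#>  crPWV  0.9996666  0.9972134 60
#>  cfPWV  0.9994999  0.9971803 60
#>  ...
#>
#> Bland-Altman vs theoretical aoPWV (m/s):
#>  index         bias loa_half_width  n
#>  aoPWV -0.002258618     0.16834416 60
#>  cfPWV  0.099563388     0.06539138 60
#>  ...
```

Transit-time PWVs and carotid distensibility track the reference stiffness
almost perfectly on clean synthetic data (|r_s| > 0.99), distensibility
negatively; CAVI follows closely. `run_full_assessment()` can also run the
sensitivity analysis (`sensitivity = TRUE`) and the noise experiment
(`snr_levels = c(Inf, 30, 20, 15)`), and writes `panels.csv`,
`correlations.csv`, `bland_altman.csv`, `sensitivity.csv` and
`noise_robustness.csv` when `out_dir` is given.

To analyse an on-disk population instead, use
`load_population(path, format = "synthetic_csv")` (CSV + JSON-manifest
layout written by `write_population()`) or
`format = "zenodo_matlab"` for a MATLAB-container population, whose field
layout is described by `inst/extdata/zenodo_matlab_mapping.json`.

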