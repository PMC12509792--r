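# gibct

Design optimization and in-silico simulation of grating-interferometry
breast CT (GI-BCT) in R.

Talbot-Lau grating interferometry adds a refraction channel to breast CT:
soft-tissue contrasts that nearly vanish in attenuation survive in the
refractive index decrement δ. But the analyzer grating absorbs half of
the beam, gold gratings can only be etched up to an aspect ratio of about
50, and clinical rooms cap the system length — so the design question is
whether, and for which imaging tasks, the refraction channel pays for its
dose. `gibct` is written for medical-imaging physicists who want to
answer that question quantitatively: it scores candidate interferometers
with a joint metric, searches the constrained design space exhaustively,
and verifies the shortlisted systems with a full noise-resolved imaging
simulation.

## The metric

For a spherical lesion of radius *r*, the detector-integrated signals are
a volume effect in attenuation and a surface effect in refraction,

&nbsp;&nbsp;&nbsp;&nbsp;S\_T = (4/3)·π·r³·Δμ,&nbsp;&nbsp;&nbsp;
S\_φ = 4π·r²·(d/p₂)·Δδ,

with d/p₂ the interferometer sensitivity (rotation-centre-to-G2 distance
over analyzer pitch). With photon-counting noise σ\_T = 1/√I\_D and
σ\_φ = 1/(√I\_D·V\_eff), the figure of merit is the contrast-to-noise
ratio weighted by dose,

&nbsp;&nbsp;&nbsp;&nbsp;CNRD = (S\_T/σ\_T + S\_φ/σ\_φ) / Dose^q,

evaluated with spectrum-weighted effective contrasts under beam
hardening, the analytic Talbot-Lau visibility spectrum, and
grating-transmission penalties. The surface-versus-volume scaling makes
refraction dominate small lesions and attenuation large ones — the
crossover is the clinically interesting quantity.

## Worked example

Solve the optimized geometry (5.3 um pitches, third Talbot order, 38 keV
design energy) and score it for a 0.25 mm malignancy in a 14 cm breast
at 50 kVp:

```r
library(gibct)
g <- solve_geometry(design_point(5.3, 3, 38))
g
#> <bct_geometry> TO 3 @ 38 keV
#>   pitches p0/p1/p2: 5.300 / 5.300 / 5.300 um
#>   L 0.6457 m, D 0.6457 m, S 1.2914 m (total 1.4414 m)
#>   source-sample 0.8957 m, sample-G2 0.5457 m

signal_budget(g, task_spec(breast_diameter_cm = 14,
                           malignancy_radius_mm = 0.25), kvp = 50)
#> <bct_budget> 50 kVp: CNRD = 1.306e-07
#>   attenuation term 3.137e-08, refraction term 3.502e-08, Veff 0.275
#>   dmu_eff -0.01144 /cm, ddelta_eff 3.76e-09, dose 0.2584, ID 0.001756
```

The symmetric Talbot solution lands at 89.6 cm source-to-sample and
54.6 cm sample-to-detector. For this small lesion the refraction term
(3.50e-08) outweighs the attenuation term (3.14e-08); rerun with
`malignancy_radius_mm = 0.75` and the ordering flips — the
surface-to-volume argument in numbers. The budget also reports the
spectrum-weighted contrasts (note the negative Δμ but positive Δδ for
the fibroglandular/tumor pair: the channels see inverted contrast) and
the effective visibility after the sample.

Search the whole constrained space and pick the best design per tube
voltage:

```r
designs <- enumerate_feasible(search_space())   # 2561 feasible designs
best <- best_per_voltage(designs, task_spec(14, 0.25))
```

Simulate the benchmark systems on a procedural breast phantom and
extract the dose-versus-resolution curve (kernel FWHM needed for CNR 5):

```r
run_simulation(list(systems = c("gi_bct", "ab_ct"),
                    doses_mGy = c(5, 20, 80), diameter_cm = 12,
                    seed = 1, profile = "ci", out_dir = "run"))
```

Command-line wrappers for both workflows live in `inst/cli/`.

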