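---
title: "Methods: joint refraction/attenuation design optimization and in-silico evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint refraction/attenuation design optimization and in-silico evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gibct)
```

## The design problem

A Talbot-Lau interferometer adds a refraction channel to breast CT: a
source grating G0 creates an array of mutually incoherent line sources, a
pi-shifting phase grating G1 forms a self-image at a fractional Talbot
distance, and an analyzer grating G2 samples that pattern. Translating a
grating over one pitch while recording intensities (phase stepping) yields
per-pixel transmission, differential phase, and fringe visibility. The
refraction signal is attractive because soft-tissue contrasts that nearly
vanish in attenuation survive in the refractive index decrement
$\delta$ — but the analyzer grating absorbs half of the transmitted beam,
so the channel is bought with dose.

The package's design metric weighs both channels at once. For a spherical
lesion of radius $r$ the *total* detector-integrated signals are

$$S_T = \tfrac{4}{3}\pi r^3\,\Delta\mu, \qquad
  S_\phi = 4\pi r^2\,\frac{d}{p_2}\,\Delta\delta,$$

a volume effect for attenuation and a surface effect (weighted by the
sensitivity $d/p_2$, with $d$ the rotation-centre-to-G2 distance) for
refraction. With counting-noise terms $\sigma_T = 1/\sqrt{I_D}$ and
$\sigma_\phi = 1/(\sqrt{I_D}\,V_{\mathrm{eff}})$, the figure of merit is
the contrast-to-noise ratio weighted by dose,

$$\mathrm{CNRD} = \Big(\frac{S_T}{\sigma_T} +
  \frac{S_\phi}{\sigma_\phi}\Big)\,\mathrm{Dose}^{-q}.$$

**The dose exponent.** The reference design study prints the metric with a plain
division by dose; its accompanying prose, however, demands a quantity
independent of the absolute number of incident photons. Since the CNR
grows with $\sqrt{N}$ while dose grows with $N$, only $q = 1/2$ delivers
that invariance; `task_spec(dose_exponent = )` defaults to `0.5` and also
accepts `1` as the strict-as-written alternative. A unit test pins the
scaling $\mathrm{CNRD} \propto c^{1/2-q}$ under a $c$-fold intensity
rescale for both modes. Design *rankings* at fixed task are identical in
both modes up to the monotone transform, so the choice does not move the
argmax at a fixed diameter.

**Signal-term prefactors.** The absolute prefactors of $S_T$ and
$S_\phi$ (and the relative weighting between them) are kept exactly as
above. Rankings are invariant under a common rescale; the relative
weighting matters only through the crossing radius at which attenuation
overtakes refraction, which the acceptance checks probe at 0.25 mm and
0.75 mm.

## Geometry, constraints, spectra

Given the G0 pitch $p_0$, the G0-G1 distance $L$, an odd Talbot order and
the design energy, the remaining geometry follows from
$S = L\,TO\,p_0^2/(TO\,p_0^2 - 2\lambda L)$, $D = S - L$,
$p_1 = 2Dp_0/S$, $p_2 = p_0 D/L$. At $L = TO\,p_0^2/(4\lambda)$ the
system is symmetric ($D = L$, all pitches equal); with 5.3 um pitches,
third order and 38 keV this reproduces the published 89.6 cm
source-to-sample and 54.6 cm sample-to-detector distances once the
15 cm source-G0 distance and a rotation-centre offset of half the 20 cm
field of view are added. The offset is a design decision of this package: the reference
study never states where the rotation centre sits, and FOV/2 is the smallest
offset that lets a full-field sample clear G1 while making the published
distances self-consistent.

Absorption gratings are gold with height $h_g = 3/\mu_{Au}(E_d)$
($e^{-3}$, at least 95% absorption). Feasibility gates: aspect ratio
$h_g/(p/2) \le 50$ at **both** absorbers (G0 and G2 — the inverse
geometry places the finest pitch at G0, so $p_2 \ge p_0$ is enforced as
well), a solvable geometry, and a total length
$0.15\,\mathrm{m} + S \le 1.45\,\mathrm{m}$. If the aspect-ratio cap
binds, the design is infeasible rather than built with reduced height.

The tube spectrum is an analytic model: Kramers bremsstrahlung
$w(E) \propto (kVp/E - 1)$ with Thomson-Whiddington anode
self-filtration (take-off 12 degrees, $C_{TW} = 7\times10^5$
keV$^2$cm$^2$/g — photons of energy $E$ are created down to the depth
where the electron beam has slowed to $E$) and Beer-Lambert aluminium
filtration, on 1 keV bins from 8 keV. Characteristic K lines are omitted:
tungsten's K shell (69.5 keV) is barely excited at up to 70 kVp, and the
L lines are removed by 3 mm of aluminium. The resulting 50 kVp + 3 mm Al
mean energy is 32.5 keV, in the range produced by established spectrum
generators; `load_spectrum_csv()` accepts external spectra for bit-exact
substitution.

Material data ship as packaged tables computed from atomic cross
sections (Cromer-Liberman photoelectric, binding-corrected Klein-Nishina
incoherent, IT92-form-factor coherent) for documented elemental
compositions; provenance sits in each CSV header. Refraction uses
phase-contrast Hounsfield values $HU_p$,
$\rho_e = (1 + HU_p/1000)\rho_{e,\mathrm{water}}$ and
$\delta = r_0\lambda^2\rho_e/2\pi$ — note $\delta \propto E^{-2}$, which
the implementation enforces (a linear-in-$E$ variant is dimensionally
untenable). The packaged $HU_p$ values (adipose $-83$, fibroglandular
$+55$, tumor $+31$) are representative of published phase-contrast breast
measurements and deliberately encode the inverse fibroglandular/tumor
contrast between the channels (tumor denser in $\mu$, fibroglandular
higher in $\delta$); they are user-replaceable, since the literature
spread is substantial.

## The grid search and the published combination count

`enumerate_feasible()` walks design energy (20-46 keV, 1 keV), G0 pitch
(3-10 um, 0.1 um), G0-G1 distance (10-100 cm, 500 um) and Talbot order
{1,3,5,7} in the flowchart order, by integer index (no floating-point
drift). Because sensitivity $d/p_2$ grows monotonically with $L$, the
feasible $L$ values per $(E_d, p_0, TO)$ form an interval computed in
closed form; the default `per_design` mode keeps the
sensitivity-maximizing endpoint, while `per_tuple` counts every feasible
grid tuple. Under the full gate set the defaults yield 2561 designs
(413121 tuples). The reference design study reports 393 distinct combinations
for this space; none of the documented readings of the grid (tuples,
designs, symmetric-only solutions, with or without the analyzer gates)
reproduces that figure, so both counts are reported and the discrepancy
is left open rather than absorbed into a tuned constraint.

`best_per_voltage()` evaluates the CNRD of every design over 25-70 kVp
with cached spectral integrals; ties break deterministically toward
smaller design energy, pitch and length. The optimal voltage rises with
breast diameter, and the refraction term dominates small lesions while
attenuation wins for large ones — both asserted as acceptance
properties.

## In-silico chain

The evaluation surface is the 2D central slice in fan-beam geometry (the
reference study ran cone beam through an external engine; on the central
slice the two coincide). The forward projector accumulates per-material
ray path lengths once (nearest-neighbour sampling at half-pixel steps),
making every per-energy sinogram a matrix product. Attenuation sums
spectrum-weighted per-energy transmissions. Refraction hardens the
spectrum per ray, weights it by the analytic visibility spectrum
$V(E) = \frac{2}{\pi}\sin^2(\pi E_d/2E)\,|\sin(\pi TO E_d/2E)|$ (an
upper envelope — the absolute value discards non-physical negative
lobes — scaled by an empirical quality factor $Q = 0.65$), and combines
per-energy phase gradients as the argument of the phasor sum. A 1-pixel
FWHM Gaussian along the detector axis matches the refraction channel's
modulation transfer to attenuation (the original kernel came from
wave-optics runs that are not public; the value is configurable), and
fringe visibility is damped by
$\exp(-(c_r\,|\partial_x P_\delta|)^2/2)$, $c_r = 1$ pixel/rad by
default, which leaves smooth anatomy untouched and dips at edges.

Phase stepping follows
$I_k = P_\mu \bar c (1 + V D_{\delta''}\cos(P_\delta + 2\pi k/N))$ with
Poisson draws; $N = 5$ by default (the minimum 3-parameter retrieval
plus margin; the reference study does not state N). Retrieval is the DFT over
steps; the sign convention is pinned by the exact noiseless round trip
for $N \in \{3,4,5,8\}$. Flat fields are noiseless by default (a noisy
mode exists). The retrieved-phase noise follows
$\sqrt{2}/(V\sqrt{I})$ — the $\sqrt 2$ is the first-harmonic
perturbation constant, verified by Monte Carlo — and saturates at the
uniform-distribution limit $\pi/\sqrt{3}$ when photons run out; the
design-level noise terms keep the conventional $1/(V\sqrt I)$ form,
whose constant cancels in rankings. The low-dose usability gate is
$\sigma_\phi \le (\pi/\sqrt 3)/2.5$ (inclusive); the
$\pi/\sqrt 3$ form is used rather than a typeset $\pi/3$, which drops
the root of the uniform-distribution variance.

Dose-to-photon budgeting is a simplified calorimetric calibration: the
energy absorbed in a water cylinder of the breast diameter (one
detector-row slice high) over the whole scan equals dose times mass;
grating transmission (open fraction plus Beer-Lambert through the
lamellae; silicon pi-shift comb for G1) then discounts the detected flat
counts. The gratingless benchmark keeps the full flux — the dose penalty
of the analyzer is thereby represented, while absolute dosimetry against
physical measurements is out of scope.

FBP uses cosine-weighted, Ram-Lak-filtered fan-beam backprojection with
$1/U^2$ distance weights for attenuation, and Hilbert filtering
($q = H[g']/2\pi$, $1/U$ weights — the Hilbert kernel scales as $1/s$
under magnification where the ramp scales as $1/s^2$) for the
differential phase channel, inverting the $2\pi d/p_2$ sensitivity so
the image is in $\delta$ units. Analytic-disc oracles bound the centre
error at 2% (attenuation) and 3% (refraction, at 200 um detector
sampling); the residual refraction bias is the finite-difference
gradient transfer plus the small-fan Hilbert approximation.

## Fusion and evaluation

Each channel is normalized per tissue pair so the higher-valued tissue
reads 1 and the lower 0 (channel-wise — an inverse-contrast channel gets
a negative gain, the simple strategy's documented failure mode in
heterogeneous scenes). Fusion sums the Gaussian low-pass of attenuation
with the complementary high-pass of phase at a shared kernel; the kernel
is chosen by minimizing the fused-image variance over a homogeneous
reference patch (a proxy for the integrated noise power spectrum, whose
exact original criterion is not public) on a geometric sigma grid. The
filtering is periodic-FFT with exact unit DC gain, so the frequency
split is exactly complementary.

CNR uses the pooled two-ROI standard deviation (the estimator is not
specified in the source; a single-ROI variant is a one-line change), and
the resolution-versus-dose analysis finds, by bracketing and bisection,
the smallest isotropic Gaussian FWHM reaching CNR 5 (Rose criterion)
between tissue ROIs, then fits FWHM against dose with a first-degree
polynomial; rendering kernels come from the fitted line so single noisy
outliers do not blur displayed images.

## The phantom

`build_phantom()` emulates the evaluation phantom: an adipose disc, a
fibroglandular compartment obtained by thresholding two-scale
band-pass-filtered white noise at the quantile that hits a target
glandular area fraction (default 40% — the original fraction is not
stated; 40% sits in the mammographically "heterogeneously dense" range),
one large tumor region, and small tumor inserts (defaults 1.0/0.5/0.25
mm) placed both in a pure-adipose pocket and in a solid fibroglandular
island, with recorded ROIs. Structural scales follow the diameter;
insert radii stay absolute. The texture is an *emulation* — visually
dendritic and statistically controllable, but no claim of equivalence
to any particular clutter model is made, so passing tests speak to the
pipeline's noise and resolution behaviour, not to observer performance
on real anatomy.

## Problem sizes and profiles

Two profiles bundle the simulation scale: `full` (200 um detector
pixels, 1000 projections, 0.1 mm phantom grid, 512 px reconstructions)
mirrors the nominal acquisition; `ci` (600 um, 320 projections, 0.5 mm
phantom grid, 220 px reconstructions, 1 mm inserts only) is the
package's routine-testing scale, chosen so the complete three-system,
three-dose evaluation runs in minutes on one core while preserving
every modelling step. Reference ROIs (not the sub-millimetre inserts)
carry the CNR analysis on the `ci` profile.

## Known limitations

No scatter, no detector response (MTF of 1), no dark-field channel or
microcalcifications, no grating-imperfection modelling beyond the scalar
quality factor, relative (not absolute) dosimetry, and the two-material
normalization's inverse-contrast fragility discussed above. The
published combination count (393) remains unreproduced under every
documented reading of the search grid.
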