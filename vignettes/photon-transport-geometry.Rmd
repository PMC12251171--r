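---
title: "Photon transport and sensor geometry in reflective PPG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon transport and sensor geometry in reflective PPG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Reflective photoplethysmography (PPG) places a light source and a
photodetector side by side on the skin. Photons that reach the detector
have travelled through tissue along the characteristic arc-shaped
("banana") region between the two spots. The DC level of the detected
signal, the optical path length through tissue, and the depth the
detected photons reach all depend on the sensor geometry: the
source-detector distance $d$ and the tilt angles of source and detector.
`ppgmc` simulates this dependence for a well-characterised laboratory
scene — a homogeneous porcine-skin phantom covered by microscope slides,
a thin air gap and an opaque optical barrier — so that geometry effects
can be explored without the variability of in-vivo measurements.

The quantities of interest are:

* **DC level** $\bar S$: the summed detected packet weight per launched
  photon (the quasi-static component of the PPG signal).
* **Differential pathlength factor** $\mathrm{DPF} = \bar l / d$, the
  weight-averaged optical path length $\bar l$ of detected photons in
  the phantom divided by the source-detector distance. In a
  non-scattering medium light travels straight, $l = d$ and
  $\mathrm{DPF} = 1$; scattering makes $\mathrm{DPF} > 1$.
* **Mean maximum penetration depth**: the weight-averaged greatest depth
  attained by detected packets.
* **Photon-density maps**: the (x, z) distribution of detected-photon
  path segments — the banana region made visible.

## Scene model

Coordinates are in mm: origin at the phantom surface midway between the
source and detector spots, $+z$ into the phantom, $+x$ from source spot
to detector spot. The phantom is an analytic homogeneous cylinder
(radius 25 mm, height 50 mm) below the surface plane. Above it sit, in
order: a thin air gap (default 0.02 mm — the laboratory setup could not
exclude one, so a thin but nonzero default is used; configurable), a
1 mm glass slide layer, and ambient air. An opaque barrier, 0.5 mm thick
and centred at $x = 0$, separates the source and detector sides from the
phantom surface up to the top of the slides; it absorbs every packet
that enters ("perfect absorber"), which is its laboratory function of
blocking direct cross-talk.

Two geometric choices deserve comment:

* **Barrier height.** The barrier defaults to being flush with the
  slide top. A barrier extending above the slides would physically
  occlude the oblique collimated beam for strongly negative source
  angles (the beam crosses the $|x| < 0.25$ mm band above the slides
  before refracting down to the spot), which would extinguish the signal
  in exactly the configurations where the published negative-angle
  behaviour shows a finite minimum. The height above the slides is a
  parameter (`barrier_height_above`) for sensitivity studies.
* **Analytic surfaces, voxel grid as a product.** The transport kernel
  traces the exact planes, box and cylinder of the scene, because
  Fresnel refraction needs exact interface normals and the air gap is
  thinner than any practical voxel. The voxelized superstructure
  (`scene_voxel_grid()`, default 0.1 mm edge — finer than the 0.5 mm
  barrier; 0.2154 mm reproduces a 0.01 mm³ voxel volume) is sampled from
  the same material map and is used for audits, maps and provenance
  export, so the two representations cannot drift apart.

Optical parameters (absorption `mu_a`, reduced scattering
`mu_s_reduced`, anisotropy `g`, index `n`) for the phantom and the glass
at 520, 637 and 940 nm are the characterised values shipped in
`optical_table`. The phantom is the only scattering medium; glass is
attenuated by Lambert-Beer along the traversed chord; air layers are
lossless.

## Transport kernel

The kernel implements the standard weighted photon-packet random walk:

* Free paths are sampled as dimensionless optical depth
  $\tau = -\ln u$ and consumed against $\mu_t = \mu_a + \mu_s$ along the
  ray; leftover $\tau$ is carried across interfaces rather than
  resampled, which keeps the walk unbiased in heterogeneous media.
* At a scattering site the packet deposits
  $\Delta w = w\,\mu_a/\mu_t$ and is deflected by the active phase
  function; the direction is renormalized after every spin.
* In non-scattering media (glass, air, or a phantom configured with
  $\mu_s = 0$) no interactions are sampled: the packet moves straight to
  the next interface under continuous Lambert-Beer attenuation, which
  makes the non-scattering limit ($\mathrm{DPF} = 1$,
  $T = e^{-\mu_a t}$) exact rather than statistical.
* Interfaces use the unpolarized Fresnel average with a statistical
  reflect/refract decision; total internal reflection returns
  reflectance 1.
* Packets below weight $10^{-4}$ play Russian roulette (survival
  probability 1/10, survivors multiplied by 10) — the conventional
  unbiased termination; both parameters are configurable.
* Path length and maximum depth accumulate only inside the phantom:
  DPF is a tissue-path quantity, so glass and air chords are excluded.
* Packets crossing the lateral cylinder wall or the bottom terminate
  (`side_exit`); in this geometry they cannot reach the detector, which
  matches the observation that the phantom edge does not shape the
  banana.
* A per-photon event cap (default $10^6$) guards against pathological
  trajectories; capped photons are booked as absorbed and counted.

Every launched unit of weight is accounted for:
detected + escaped + side-exit + deposited + barrier-absorbed +
(roulette killed − roulette boosts) equals the launched weight to
floating-point precision, and the net roulette adjustment is itself a
mean-zero statistic. `energy_audit()` exposes this identity.

The RNG is xoshiro256++ seeded by splitmix64 from a (seed, stream) pair.
Each (wavelength, distance, angles, replicate) configuration hashes to
its own stream, so results are bitwise reproducible and independent of
sweep order.

## Source and detector

The collimated emitter (0.2 mm facet, magnification 3.05) produces a
0.610 mm beam. Photons are sampled uniformly over the beam cross-section
projected onto the surface (an ellipse with major axis
$0.610/\cos\theta_s$ mm), started in ambient air above the slides, and
the chief ray is aimed so that after refraction through glass and gap it
lands on the designated spot centre at $x = -d/2$. Angle changes
therefore never move the spot, and distance changes never alter the
angles — the alignment convention of the laboratory frame.

The detector is modelled at the phantom surface: a 0.55 mm spot
(projected to an ellipse at $\theta_d$) centred at $x = +d/2$, plus an
acceptance cone about the detector's optical axis. The lens (10.9 mm),
fibre (0.2 mm) and magnification (2.76) are carried as metadata; the
working distance is not published, so the acceptance half-angle cannot
be derived and is an explicit parameter (default 15°), with
`detector_accepts()` and the `alpha` control available for sensitivity
sweeps.

**Sign conventions** (the x-z plane, +x from source to detector):

| angle | positive | negative |
|---|---|---|
| $\theta_s$ | beam axis tilts toward the detector | away from the detector |
| $\theta_d$ | viewing axis (lens→spot) points toward the source; accepted photons leave travelling away from the source | viewing axis points away from the source |

The convergent ("toward each other") arrangement is the positive one.
Note the asymmetry of the detector convention: because detection is
about the direction photons *leave* along, the accepted exit directions
for positive $\theta_d$ have a $+x$ component. Reading the convention
the other way inverts every detector-angle trend against the laboratory
behaviour and would place the barrier inside the detector's line of
sight for $\theta_d \gtrsim 36°$ at $d = 2$ mm.

## Phase functions

Two backends provide the scattering deflection:

* **Henyey-Greenstein** with the characterised anisotropy
  $g = 0.550$, sampled by the closed-form inverse CDF.
* **Mie** for the phantom's 250 nm TiO₂ scatterers. The relative index
  uses DeVore's rutile ordinary-ray dispersion
  ($n^2 = 5.913 + 0.2441/(\lambda^2 - 0.0803)$, $\lambda$ in µm) for the
  particle — rutile is the common pigment-grade form; no comparable
  single-term dispersion exists for anatase, so a user-supplied particle
  index serves that case — and the phantom index for the host. The
  phase function is tabulated from the Mie series on 2048
  Gauss-Legendre nodes in $\cos\theta$ (dense near the forward peak),
  normalized so $\int p \,\mathrm d\cos\theta = 1$, and sampled by
  linear-interpolated inverse CDF — the same sampler in R and in the
  kernel. Below size parameter $x = 0.1$ the series coefficients are
  replaced by their leading-order small-sphere expansions, because the
  Bohren-Huffman recurrences lose $b_1$ (an $O(x^5)$ quantity obtained
  as the difference of $O(x)$ terms) to cancellation; this branch
  reproduces the Rayleigh dipole limit exactly.

When the Mie backend is active, the $\mu_s' \to \mu_s$ conversion uses
the Mie-computed $\langle\cos\theta\rangle$ instead of 0.550, keeping
the measured transport scattering $\mu_s'$ fixed — the characterisation
constrains $\mu_s'$, not $\mu_s$.

## Experiments and estimators

`run_configuration()` runs `n_seeds` independent replicate streams
(default 5) of a per-configuration photon budget $N(d) = N_0\, d /
d_\min$ (default $N_0 = 2\times10^6$ at $d_\min = 2$ mm, split evenly
over seeds). The linear growth with $d$ compensates the loss of
detected packets at wide separations. Estimators:

* $\bar S$ = mean over seeds of detected weight / photons launched;
  its standard error comes from the seed spread.
* DPF and mean maximum depth are weight-averaged over detected packets
  and pooled across seeds (each packet contributes its weight, the same
  weighting that defines the DC level); per-seed values provide the
  standard errors. A configuration with zero detections is flagged and
  carries an undefined (NA) DPF rather than a silent zero.
* `normalize_sweep()` divides each (wavelength, distance) cell by its
  reference configuration — (15°, 25°) on the positive branch and
  (−15°, −25°) on the negative branch — giving $\bar S' = 1$ exactly at
  the reference. Normalization is applied to the seed-mean.
* `distance_attenuation()` is the mean over matched positive-angle
  configurations of $\bar S(5\,\mathrm{mm})/\bar S(2\,\mathrm{mm})$ —
  the "average factor" interpretation of the reported distance decay;
  the per-configuration ratio is averaged, not the ratio of averages.
* `run_density_map()` accumulates detected packets' in-phantom path
  segments on an (x, z) grid, each cell receiving weight × path length
  in the cell; `normalize_density()` scales by the maximum of a
  designated reference map (by convention the map is normalized to the
  maximum of the visualised data).

```{r}
library(ppgmc)
r <- run_configuration(520, 2, 15, 25,
                       control = run_control(photons_base = 2e6))
print(r)
```

## What the checks show — and what they do not

The scene is a homogeneous epoxy phantom, not skin: no layers, no
melanin, no pulsatile blood, a perfectly planar polished surface, a
perfectly collimated source. Passing the package's checks therefore
demonstrates that the transport kernel and the geometry model are
correct and that the *geometry trends* of a reflective sensor are
reproduced; it does not validate any claim about layered human skin or
AC/perfusion signals, which need richer tissue models.

Two laboratory parameters are genuinely unknown: the air-gap thickness
("could not be excluded" — default 0.02 mm) and the detector acceptance
half-angle (default 15°). Absolute DC levels depend on both, so
quantitative comparisons are made on normalized levels, ratios and
path-length quantities, which are far less sensitive; the
distance-attenuation factors are reproduced within the stated
factor-of-two band (and in practice within ~10%) without tuning either
parameter.

Problem sizes: the bundled checks run the reduced angle grid
{(15,25), (35,35), (55,55)} plus single-axis and negative-angle spurs at
$6\times10^5$ photons per configuration over 5 seeds; the acceptance
script runs the reduced grid at the full desk scale ($2\times10^6$ to
$5\times10^6$ photons per configuration, 5 seeds). Trend checks use a
3-standard-error statistical tolerance over seeds; they are engineering
acceptance checks, deliberately without multiple-comparison
adjustment.

## Numerical choices

* Boundary stepping pushes the packet $10^{-7}$ mm past each interface
  to avoid re-intersection; the resulting path-length bias is below
  $10^{-6}$ relative and is covered by the non-scattering-limit check.
* Direction renormalization after every deflection keeps $|\hat u| = 1$
  to machine precision over millions of events.
* The Mie CDF endpoints are pinned to exactly 0 and 1; interior values
  come from trapezoidal integration on the (dense) node grid.
* The diffusion-theory reflectance (`diffusion_reflectance()`, a
  Groenhuis-style closed form with the polynomial internal-reflection
  parameter) is used only as an order-of-magnitude cross-check at ±30%:
  the real scene departs from the semi-infinite half-space it assumes.
* Degenerate inputs fail loudly: unsupported wavelengths, $g = 1$,
  voxel edges coarser than the barrier, missing normalization
  references, and empty density maps all raise classed errors.

## Known limitations

* The detector is a surface spot + cone, not an imaging train; lens
  aberrations and defocus at tilted geometries are not modelled.
* The collimated source has zero divergence; a real LED's Lambertian
  profile would soften all angle trends.
* Polarization is ignored (unpolarized Fresnel averages, scalar Mie
  phase function), and scatterers are monodisperse.
* Time-resolved transport and fluorescence are out of scope.
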