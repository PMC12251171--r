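# ppgmc — Monte Carlo photon transport for reflective PPG sensor geometry

Reflective photoplethysmography (PPG) sensors — the optical pulse
sensors in wearables — place a light source and a photodetector a few
millimetres apart on the skin. The photons that make it back to the
detector traverse tissue along the arc-shaped "banana" region between
the two spots, and the sensor geometry (source-detector distance *d*,
signed source angle θs, signed detector angle θd) controls how much
light is detected and how deep it travelled.

`ppgmc` is a photon-packet Monte Carlo simulator of a laboratory
characterisation scene for this problem: a homogeneous porcine-skin
phantom (cylinder, radius 25 mm, height 50 mm) covered by a thin air
gap, a 1 mm microscope-slide glass layer, and an opaque optical barrier
centred between the spots to block direct cross-talk. For any
(wavelength, d, θs, θd) configuration at 520, 637 or 940 nm it
computes:

* the **DC signal level** S̄ — summed detected packet weight per
  launched photon;
* the **differential pathlength factor** DPF = l̄ / d, where l̄ is the
  weight-averaged optical path of detected photons in the phantom
  (Lambert-Beer holds with DPF = 1 in non-scattering media);
* the **mean maximum penetration depth** of detected photons;
* **photon-density maps** of the banana region;

with normalized sweep tables S̄′ = S̄ / S̄(reference) (reference
(15°, 25°) for positive angles, (−15°, −25°) for negative), linear
photon-budget scaling N(d) = N₀·d/d_min, replicate-seed averaging, and
Henyey-Greenstein or Mie (250 nm TiO₂, DeVore rutile dispersion) phase
functions. The transport kernel (Rcpp) does weighted-packet transport
with carried optical depth across interfaces, unpolarized
Fresnel/Snell boundary events, Lambert-Beer attenuation in
non-scattering media, Russian roulette, and a perfectly absorbing
barrier.

## Worked example

```r
library(ppgmc)
r <- run_configuration(520, 2, 15, 25,
                       control = run_control(photons_base = 6e5,
                                             n_seeds = 5, seed = 1))
print(r)
#> PPG MC configuration: 520 nm, d = 2 mm, theta_s = 15, theta_d = 25 (hg)
#>   photons: 600000 over 5 seeds; detected packets: 97
#>   DC level S-bar = 6.721e-05 (se 1.1e-05)
#>   DPF = 3.217, mean max depth = 1.054 mm
```

About 7 detected weight units per 10⁵ launched photons reach the
detector at this geometry; the detected light travelled on average 3.2
times the 2 mm spot separation through the phantom and reached about
1 mm deep. Sweeps and normalization:

```r
cfg <- sweep_config(wavelengths = c(520, 940), distances = c(2, 5),
                    theta_s = c(15, 35, 55), theta_d = c(25, 35, 55),
                    control = run_control(photons_base = 2e6, seed = 1))
sw  <- normalize_sweep(run_sweep(cfg))
distance_attenuation(sw, 520)   # mean S(5 mm)/S(2 mm), positive angles
write_outputs(sw, "out/")       # sweep.csv, counts.csv, metadata.json
```

Simulated geometry trends (reduced grid, 520 nm, d = 2 mm, HG backend):
the DC level rises monotonically from the divergent (−55°, −55°)
configuration to the convergent (55°, 55°) one, while DPF falls from
≈ 4.5 to ≈ 2.6 and the mean maximum depth from ≈ 1.4 mm to ≈ 0.9 mm —
pointing source and detector toward each other buys signal at the cost
of path length and depth, and negative angles do the reverse.

A density map of the banana region:

```r
m <- normalize_density(run_density_map(520, 2, 15, 25,
        control = run_control(photons_base = 1e6)))
plot(m)   # log-scaled (x, z) map, max cell = 1
```

A thin CLI wraps the same functions
(`inst/cli/ppgmc.R simulate|sweep|density-map|oracle-report`, YAML run
configs as in `inst/extdata/example-run.yaml`).

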