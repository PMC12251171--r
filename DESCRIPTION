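Package: ppgmc
Title: Monte Carlo Photon Transport for Reflective PPG Sensor Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Surface- and voxel-based Monte Carlo simulation of photon
    migration in a homogeneous porcine-skin phantom covered by microscope
    slides, an air gap and an opaque optical barrier, replicating a
    reflective photoplethysmography (PPG) laboratory scene. Simulates the
    detected DC signal level, differential pathlength factor (DPF), mean
    maximum penetration depth and photon-density ("banana") maps as
    functions of wavelength, source-detector distance and signed source
    and detector angles, with Henyey-Greenstein and Mie phase-function
    backends, Fresnel/Snell boundary handling and Russian-roulette
    termination.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
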