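# adiposim

Light transport and OCT image simulation in adipose cell layers.

White adipose tissue is a close packing of cells whose volume is almost
entirely one lipid droplet (n = 1.46) in interstitial fluid
(ISF, n = 1.36–1.40). At near-infrared wavelengths each cell acts as a
wavelength-scale lens: a focused beam crossing a few cell layers is split
into narrow photonic jets and bright hot spots instead of being diffusely
scattered, and the droplet/ISF index mismatch controls how much light gets
through. Physiological heating releases lipids into the interstitial space,
raises the ISF index, and optically clears the tissue. `adiposim` is for
researchers in tissue optics and OCT who want to simulate and quantify this
regime.

The package provides:

* **Geometry** — three-shell cell models (`make_cell()`), regular and
  ~20%-jittered lattices (`build_lattice()`, `build_lattice_3d()`), and
  rasterized refractive-index maps (`rasterize()`).
* **Forward solvers** (`solve_forward()`) — a convergent Born series
  full-wave Helmholtz engine (scattered-field formalism, absorbing
  boundaries, FFT-preconditioned) and a fast unidirectional split-step
  engine; windowed collimated transmittance (`transmitted_fraction()`) and
  hot-spot detection (`find_hotspots()`).
* **Analytic theory** — Bouguer–Beer–Lambert transmittance with the
  Mie-estimate scattering coefficient
  `mu_s = a^2 rho_s (n_LD/n_ISF − 1)^2` and its exact inversion to the
  relative refractive index (`transmittance()`,
  `relative_index_from_T()`).
* **OCT synthesis** — wave Monte-Carlo A-/B-/C-scans: spectral split-step
  propagation, gradient-derived local reflectance, backward propagation,
  interference with the reference beam, ensemble averaging and the
  `W = log10(1 + W_oct(z)/W_oct(0))` transform (`synthesize_ascan()`,
  `scan_raster()`).
* **Image statistics** — relative brightness dispersion `D_b`,
  noise-referenced contrast stretching, group averaging, bottom-interface
  profiles and 20-µm windowed intensity ratios.
* **Reproducible experiments** — YAML run configurations, preset pipelines
  with checksummed manifests (`run_experiment()`), seeded fixture
  generators with analytic oracles, and a thin command-line front end
  (`inst/cli/adiposim`).

## Worked example

Collimated transmittance of a six-layer cell stack before and after
index-matching, against the analytic estimate:

```r
library(adiposim)

solve_T <- function(n_isf) {
  lat <- build_lattice(make_cell(), n_layers = 6, cells_per_layer = 10,
                       n_ISF = n_isf, packing = "hexagonal")
  fld <- rasterize(lat, grid_spacing = 0.08, domain_padding = 40)
  transmitted_fraction(solve_forward(fld, beam_spec(), dz = 0.1))$T
}
T36 <- solve_T(1.36)   # uncleared tissue
T40 <- solve_T(1.40)   # heated / index-matched tissue
c(T36, T40, ratio = T40 / T36)
#> [1] 0.4229  0.5428  1.2836
transmittance(n_LD = 1.46, n_ISF = c(1.36, 1.40), l = 120)
#> [1] 0.5227 0.8022
```

The lattice solve says 42% of the beam power crosses a 20 µm exit window at
n_ISF = 1.36 and 54% after clearing to 1.40 — a 1.28-fold gain from a 0.04
index shift, the optical-clearing effect. The single-scattering
Beer–Lambert estimate (52% and 80%) is systematically higher because it
ignores beam splitting and sideways channelling.

Inverting a measured in vivo transmittance to the droplet/ISF index ratio:

```r
relative_index_from_T(c(0.394, 0.401, 0.414), l = 120)
#> [1] 1.0881 1.0873 1.0857   # heating matches the indices
```

An OCT A-scan with the beam centred on a cell column shows paired echoes
from each cell's top and bottom boundary; between columns only the side
borders reflect:

```r
lat <- build_lattice(make_cell(), n_layers = 8, cells_per_layer = 10,
                     n_ISF = 1.36, packing = "square")
src <- oct_source(n_spectral_samples = 128)
x0 <- lat$centers$x[lat$centers$layer == 1][5]
sc <- synthesize_ascan(lat, src, beam_position = x0, grid_spacing = 0.15)
plot(sc$zeta, sc$W, type = "l",
     xlab = "optical depth (um)", ylab = "W")
```

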