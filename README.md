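# voxdose

Voxelized Monte Carlo dosimetry for solar-particle-event (SPE)
radiobiology experiments.

Large-animal SPE experiments irradiate minipig-scale subjects either with
large-field clinical electron beams (a 6 + 12 MeV mix prescribed at the
depth of maximum dose) or with low-energy protons whose energy spectrum
mimics an SPE (tens of MeV, producing strongly depth-inhomogeneous
"stopping" dose distributions).  Relating the biological outcomes to dose
requires per-organ dosimetry that measurements alone cannot provide.
`voxdose` is a desk-scale, self-contained R implementation of that
dosimetry chain, for medical physicists and radiobiologists who need
reproducible organ-dose estimates, depth-dose validation harnesses and
dose-volume histograms (DVHs) without a cluster-sized Monte Carlo stack.

## What is inside

* **Condensed-history transport** (Rcpp core) of protons and electrons in
  rectilinear voxel grids.  Protons: Bethe collision stopping power
  (no shell/density corrections, I(water) = 75 eV); electrons:
  Berger–Seltzer collision term with radiative losses `(E + m_e c²)/X₀`
  removed but not transported.  Energy-loss straggling is Gaussian with
  the Bohr width `σ_E² = 0.1569 (Z/A) ρ Δx` MeV²; multiple scattering
  uses the Highland width
  `σ_θ = 13.6 MeV/(βcp) · √(Δx/X₀) · (1 + 0.038 ln(Δx/X₀))`.
  Steps are capped at half the smallest voxel and 2% of the residual CSDA
  range; seeded batches give per-voxel mean dose and standard error.
* **Geometry**: DICOM CT import with Hounsfield-to-material conversion
  (4-bin default table, user-extensible), BODY-contour rasterization
  (even–odd rule on voxel centers) and cropping; PMMA enclosure and
  air-gap construction; programmatic phantoms including a scalable
  digital minipig-like body with skin/lungs/BFO/eyes masks.
* **Beam models**: the 2 cm disc source with 34 × 34 cm isocenter clip at
  5 m SSD for electrons (10% Gaussian energy spread), and broad parallel
  proton beams driven by a discrete spectrum file.
* **Spectrum unfolding**: a pristine Bragg-peak basis (20–80 MeV) built by
  the transport engine in a water cube, and non-negative least squares
  (`min ‖B w − d‖₂, w ≥ 0`) recovering the SPE proton spectrum from a
  measured depth-dose curve.
* **Analysis**: central-axis depth profiles (mean dose in a 5 mm-radius
  cylinder per depth slab), d_max normalization, 80/20 beam mixing,
  cardinal-angle weighting (e.g. 70% opposed-lateral + 30% opposed-AP),
  cumulative DVHs, and the enclosure air-gap comparison harness.
* **IO**: a portable binary array container, DICOM RT-Dose export
  (readable by pydicom and clinical viewers), CSV curves, YAML-configured
  experiment runs with full seed/hash logging, and a thin CLI
  (`inst/cli/voxdose`) with `phantom`, `simulate`, `unfold`, `profile`,
  `dvh` and `experiment` subcommands.

## Worked example

Simulate a monoenergetic 50 MeV proton beam in a water cube, extract the
central-axis depth-dose curve, and compare the Bragg-peak depth with the
package's own CSDA range table:

```r
library(voxdose)

cube <- make_slab_phantom("water", 10, 0.1)          # 10 cm cube, 1 mm voxels
beam <- beam_spec("proton", spectrum = spectrum(50, 1), axis = "+z")
dose <- run_transport(cube, beam, transport_config(n_histories = 2e4),
                      seed = 1, field = c(1.5, 1.5))
prof <- depth_profile(dose, axis = "z", radius = 0.5) # 5 mm cylinder average
peak <- normalize_at_dmax(prof)
cat(sprintf("peak depth %.3f cm, CSDA range %.3f cm\n",
            peak$dmax_depth, csda_range(get_material("water"), "proton", 50)))
cat(sprintf("entrance-to-peak dose ratio %.2f\n",
            prof$dose[3] / max(prof$dose)))
```

```
peak depth 2.153 cm, CSDA range 2.222 cm
entrance-to-peak dose ratio 0.21
```

The peak sits a few percent shallow of the CSDA path length — the
expected signature of multiple-scattering detour and straggling smear at
1 mm depth bins (at 0.5 mm bins the gap closes to under 2%) — and the
entrance dose is about a fifth of the peak, the classic pristine Bragg
shape.  Unfolding then works the other way around: given a measured
depth-dose curve, `build_basis()` + `nnls_fit()` return the Bragg-peak
weights, and `predict_profile()` reconstructs the curve from the fitted
spectrum:

```r
basis <- build_basis(seq(20, 80, 5), cube = make_slab_phantom("water", 10, 0.1),
                     cfg = transport_config(n_histories = 1e4))
wts <- numeric(13); wts[match(c(40, 65), basis$energies)] <- c(0.7, 0.3)
measured <- predict_profile(spectrum(basis$energies, wts), basis)
fit <- nnls_fit(measured, basis)
max(abs(fit$spectrum$weights - wts))   # 5.551115e-17: exact recovery
```

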