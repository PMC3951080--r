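---
title: "voxdose: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxdose: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`voxdose` is a desk-scale Monte Carlo dosimetry toolkit for the kind of
large-animal solar-particle-event (SPE) radiobiology experiment in which
minipigs are irradiated either with large-field clinical electron beams
(a 6 + 12 MeV mix) or with a low-energy proton beam whose spectrum mimics
an SPE.  It provides the full chain: voxelized geometry (from CT or from
programmatic phantoms), beam models, condensed-history charged-particle
transport, SPE spectrum unfolding from a measured depth-dose curve, and
depth-dose / dose-volume-histogram (DVH) analysis.  This vignette explains
the models, their assumptions, the tunable parameters, and the numerical
and design choices, in the spirit of a methods section.

## The transport model

The engine is a condensed-history class II-style simplification: it
transports primaries only (protons or electrons), grouping the many soft
collisions of a step into aggregate energy-loss and deflection samples.

Per step, limited to `min(0.5 x smallest voxel spacing, 2% of the residual
CSDA range, distance to the next voxel boundary)`:

* **Energy loss.**  Collision stopping power `S` is evaluated in the voxel's
  material at the step's starting energy.  Protons use the Bethe formula
  without shell or density corrections with `I(water) = 75 eV`; this is
  accurate to a few percent over the 1-300 MeV tabulation and reproduces
  standard CSDA ranges in water to ~0.3% over the 20-80 MeV SPE band
  (the package's own range table is the oracle used in tests).  Electrons
  use the Berger-Seltzer collision formula (Møller scattering), again
  without the density-effect correction, which biases the collision
  stopping power high by roughly 5-10% above a few MeV; depth-dose shapes
  remain realistic but absolute electron ranges are a few percent short.
* **Radiative losses (electrons).**  Approximated as
  `S_rad = (E + m_e c^2) rho / X0` and *removed* from the particle without
  being deposited - bremsstrahlung photon transport is out of scope.  The
  missing photon build-up slightly depresses dose near the entrance
  region; the energy-conservation tests therefore run with the radiative
  channel disabled.
* **Straggling.**  Gaussian with the Bohr width
  `sigma_E^2 = 0.1569 (Z/A) rho dx` (MeV^2), sampled truncated at +-3
  sigma and clamped so a step never deposits negative energy or more than
  the remaining energy.  Landau/Vavilov tails are not modeled.
* **Multiple scattering.**  Two independent transverse Gaussian angles
  with the Highland width
  `sigma = 13.6 MeV / (beta c p) sqrt(t) (1 + 0.038 ln t)`, `t` the step
  in radiation lengths; the bracket is clamped at 0.25 for extremely thin
  steps.  The direction is renormalized after deflection.
* **Termination.**  Below the cutoff (1 MeV protons, 0.2 MeV electrons)
  the residual energy is deposited locally.
* **Nuclear attenuation (optional, default off).**  A per-step survival
  probability `exp(-kappa rho_rel dx)` can crudely emulate the fluence
  loss from proton nuclear interactions; removed protons deposit nothing,
  so total energy is *not* conserved when this channel is on.  Secondary
  particles of any kind (delta rays, neutrons, photons) are not produced.

Because a step never crosses more than one voxel boundary (the boundary
distance is itself a step limit), deposits are naturally split across
voxels by geometric path length.  Dose is `MeV` deposited per voxel
divided by the voxel mass, reported in Gy per source particle.

Batches: each batch gets its own seed `base_seed + batch_index`, and
`combine_batches()` reports the per-voxel mean and standard error
(population batch spread over `sqrt(n_batches)`).  Identical seeds give
bitwise-identical dose arrays.

## Beam models

The electron source reproduces a large-field linac setup: a circular
planar source (2 cm radius) 1 m upstream of the isocenter, a square
34 x 34 cm clip at the isocenter plane and the phantom surface at 5 m SSD,
giving a ~90 cm-class field at the surface.  Primaries start on the disc
and aim at a point sampled uniformly on the clip aperture, so every
isocenter crossing is inside the field by construction; the divergence
model (uniform aim point) is this package's choice - only the source
shape, clip and distances are constrained by the setup.  The "10%
Gaussian spread" of the nominal energies (6.02 and 12.23 MeV) is
interpreted as sigma = 0.10 x nominal; a `spread_is_sigma` switch gives
the FWHM reading.

Because the clipped field's fluence is uniform over the central region
(verified to 3% in the test suite), samplers accept a *reduced aim
aperture*: histories are concentrated onto the region that actually feeds
the scoring volume without changing relative dose.  The air-gap harness
aims at the scoring cylinder plus a 2 cm lateral-equilibrium margin
(electron lateral excursions at 6 MeV are ~1 cm); the Bragg-basis builder
similarly illuminates a 1.5 cm half-width parallel field around the 5 mm
integration cylinder.

The proton beam is a broad parallel beam: uniform positions over a
rectangular face, exact beam-axis directions, energies drawn from a
discrete spectrum (the two-column spectrum file written by the unfolding
step).  Beam angles are restricted to the four cardinal directions about
the body's long axis; opposed angles mirror the source exactly, which the
symmetry tests exploit.

## Geometry and materials

CT import assigns materials by Hounsfield ranges.  The default table has
four bins (air < -950 < lung < -200 < soft tissue < +120 < bone) with
piecewise-affine density ramps that are continuous at the boundaries and
anchored at rho(0 HU) = 1.00 g/cm^3 and air at -1000 HU; an exact bin
boundary belongs to the lower bin.  The published stoichiometric
calibration schemes do not print their exact boundaries, so the default
is deliberately minimal and a full user table can be supplied as a text
file.  Voxels outside the BODY contour become air and the grid is cropped
to the BODY bounding box; a voxel belongs to a contour if its *center* is
inside the polygon (even-odd rule) - how edge-straddling voxels should be
classified is genuinely open, and center inclusion keeps rasterization
idempotent and unbiased for large structures (circle areas converge to
2% well before radius/voxel = 30).

Materials carry elemental compositions; `Z/A`, the Bragg-additivity mean
excitation energy and the radiation length are derived from element
tables at construction, with explicit `I` overrides where a standard
value exists (water 75 eV, air 85.7 eV, PMMA 74 eV).  Solid water uses
the vendor elemental analysis and density 1.04 g/cm^3 (a vendor-standard
value, overridable); PMMA is C5H8O2 at 1.19 g/cm^3.

## Phantoms

`make_slab_phantom()` builds the two standard scoring volumes (a 20 cm
solid-water cube and a 10 cm water cube) at any voxel size.
`make_airgap_rig()` places a 5 mm PMMA wall with its upstream face fixed
at z = 0 and the slab receding behind an air gap, so gap studies share a
common wall position.  `make_digital_animal()` is an idealized,
deterministic stand-in for the real animal CTs (which are not
distributed): a prolate ellipsoid of soft tissue with lateral diameter
0.55 x crown-rump length, a ~2 mm skin shell, two lung ellipsoids at
0.3 g/cm^3, a dorsal bone column plus four limb rods standing in for the
blood-forming marrow (BFO), and two eye spheres (1.5 cm radius at the
54 cm reference size).  Every proportion is a fixed fraction of the body
scale, so the 54 cm and 63 cm instances differ only by uniform
similarity - organ volumes scale as (63/54)^3 up to voxelization error,
which is what the cross-size DVH comparisons rely on.  The default 2 mm
voxel cannot resolve the 2 mm skin shell at two voxels per thickness, and
the generator warns accordingly; skin DVHs at that resolution are
single-voxel-layer estimates.

What the synthetic phantoms do *not* emulate: anatomical organ shapes,
heterogeneous marrow distribution, gas pockets, and positioning
variability of real animals.  Tests passing on these phantoms validate
the transport, scoring and analysis chain - not anatomical dose accuracy.

## Spectrum unfolding

The SPE proton spectrum is recovered from a measured depth-dose curve as
a non-negative least-squares combination of pristine Bragg peaks
(20-80 MeV in 1 MeV steps in production; the acceptance configuration
uses 5 MeV steps at 1 mm voxels to stay desk-sized).  The measured curve
is linearly interpolated onto the basis depth grid; depths outside the
measured support or beyond the deepest basis peak are trimmed, never
extrapolated.  No smoothing or regularization is applied beyond
non-negativity, matching the plain NNLS of the original workflow and
keeping entrance-region mismatches (scattered low-energy protons are not
in the basis) visible rather than hidden.  Weights are relative particle
fluences (the basis columns are dose per history, un-normalized); the
spectrum file written for the beam model is the sum-to-1 normalization.
Unweighted least squares is used - whether the original fit weighted
depth points by measurement uncertainty is unknown.

## Analysis conventions

Depth profiles average (not sum) the dose over voxels whose lateral
distance to the beam axis is at most 5 mm, per depth slab; mean and sum
differ only by a constant that normalization removes.  `d_max` is the
profile maximum, with the depth refined by the parabola through the three
samples around the discrete argmax.  Beam mixing rescales each component
so its own `d_max` dose equals its prescription fraction (e.g. 80% of
the prescription as 6 MeV and 20% as 12 MeV) before summing; angle
combination is a voxelwise weighted sum over the cardinal-angle doses
(e.g. 70% opposed-lateral + 30% opposed-AP as per-angle weights
0.35/0.35/0.15/0.15).  Both are exactly linear, tested to 1e-12.  DVHs
are cumulative (fraction of structure volume receiving at least each dose
edge), bin width `max dose / 500` by default; the DVH integral reproduces
the mask's mean dose to within binning resolution.

The air-gap harness reruns the enclosure experiment: 6.02 MeV electrons,
5 mm PMMA wall, gaps of 0-100 mm, each profile extracted inside the
phantom (depth from the phantom surface) and normalized at its own
`d_max`; the reported number is the maximum pairwise relative deviation
at `d_max`.  Because the comparison band is small (a few percent), the
harness is designed so counting statistics do not masquerade as a gap
effect: 1.2e6 histories per gap; scoring voxels of 0.5 x 0.5 x 0.2 cm
(2 mm depth resolution where the build-up needs it, coarser lateral bins
because the cylinder average is a lateral mean over a flat field); and a
7-point Savitzky-Golay quadratic smoothing of each raw profile before
normalization, which is exact for locally quadratic curves and therefore
unbiased at the broad 6 MeV maximum while suppressing per-bin noise.
With these choices the identical-geometry noise floor at `d_max` is a
few tenths of a percent per profile.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use scaled-down problem
sizes chosen as the package's own desk-scale conditions: 2 mm depth
scoring and 1.2e6 histories/gap for the air-gap study, a 13-energy basis at
1e4 histories/energy and 1 mm voxels for unfolding, 2e4 histories for
Bragg-peak localization with depth bins at ~1% of the expected range,
and 2 mm voxels for the digital animals.  Every random stage is seeded; a run is reproducible
bitwise from (seed, configuration, geometry), and `run_experiment()`
logs seeds, history counts, batch counts and the material-table hash so
any figure-analog can be regenerated from its log.

## Known limitations

* No secondary particles (delta rays, bremsstrahlung photons, neutrons,
  nuclear fragments); the optional attenuation channel only removes
  proton fluence.
* No density-effect or shell corrections in the stopping powers; electron
  collision stopping is biased high at MeV energies.
* Gaussian straggling and small-angle Gaussian scattering only; single
  large-angle scatters and range-straggling tails are absent, so distal
  falloffs are slightly too sharp.
* The digital animal is topological, not anatomical.
* DICOM support is a minimal explicit-VR little-endian subset (CT image
  read, RT-Dose write) sufficient for exchange with visualization
  software; sequences and compressed syntaxes are unsupported.
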