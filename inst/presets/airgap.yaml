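# Preset: enclosure air-gap sensitivity study.
# 6 MeV-class electron beam onto a 20 cm solid-water slab behind a 5 mm
# PMMA wall, for the eight wall-to-phantom air gaps; per-gap profiles
# normalized at their own d_max before comparison.
preset: airgap
gaps_mm: [0, 1, 3, 5, 10, 30, 50, 100]
histories: 1200000
voxel: 0.2
energy: 6.02
seed: 1
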