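# Preset: minimal slab + broad parallel proton smoke run.
name: slab_protons
phantom:
  type: slab
  material: water
  size: 10
  voxel: 0.1
beam:
  particle: proton
  energy: 50
transport:
  histories: 1000
  batches: 1
  seed: 1
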