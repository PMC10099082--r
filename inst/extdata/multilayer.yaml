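# Low-contrast multilayer target: a slow annulus around a slightly fast core,
# a regime where the straight-ray SART map is valid, so the adaptive image
# beamformed through the reconstructed map matches the one through the known
# map at the metric level (apparent sizes within a few tenths of a
# millimetre; compare the adaptive and adaptive_truth outputs).
seed: 2
geometry:
  n_elements: 64
  ring_radius: 40
  f0: 2500000
  fs: 12500000
scene:
  background_speed: 1490
  background_density: 1000
  regions:
    - shape: annulus
      center: [0, 0]
      r_in: 6
      r_out: 9
      speed: 1440
      density: 1060
    - shape: circle
      center: [0, 0]
      radius: 6
      speed: 1545
      density: 1050
sim:
  n_scatterers: 240
beamform:
  speeds: [1490, 1540]
  adaptive: true
  adaptive_truth: true
metrics:
  true_diameter: 18
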