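# 18.00 mm steel circle in water, imaged at a scaled acquisition
# (64 elements, 2.5 MHz) that runs in about a minute on one CPU.
seed: 1
geometry:
  n_elements: 64
  ring_radius: 40
  f0: 2500000
  fs: 12500000
scene:
  background_speed: 1490
  background_density: 1000
  regions:
    - shape: circle
      center: [0, 0]
      radius: 9
      speed: 5300
      density: 7850
sim:
  n_scatterers: 240
beamform:
  speeds: [1490, 1540]
  adaptive: true
  adaptive_truth: true
metrics:
  true_diameter: 18
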