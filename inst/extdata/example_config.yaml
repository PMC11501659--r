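# Example CaNTA run configuration: the reference flat-field conditions with
# a shorter acquisition (5,000 frames = 5 s) for a quick demonstration run.
# Omitted keys fall back to the packaged defaults (see default_config()).
seed: 1
optics:
  waist_radius: 4.2      # um
  wavelength: 0.532      # um
  medium_index: 1.4607
  axial_offset: 1000     # um from beam waist to channel entrance
  na: 0.25
capillary:
  channel_diameter: 4    # um
  outer_diameter: 125    # um
  cladding_index: 1.4607
liquid:
  refractive_index: 1.4607
  viscosity: 0.0033      # Pa s (water/DMSO mixture)
  temperature: 293.15    # K
particle:
  diameter: 50           # nm, gold nanosphere
acquisition:
  frame_rate: 1000       # Hz
  exposure: 0.0002       # s
  n_frames: 5000
  substeps: 10
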