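# Example run configuration: epithelial (PANC-1-like) dismountable model.
# Threshold bands are grey values (8-bit); lengths are um on the specimen
# side and mm on the model side.
preset: panc1_like
structures:
  cell_surface:
    channel: TRITC
    threshold: [80, 255]
    fill: {mode: volumetric, radius: 3}
    role: host
    color: translucent
  nucleus:
    channel: DAPI
    threshold: [80, 255]
    fill: {mode: volumetric, radius: 2}
    role: insert
    color: blue
smooth_iterations: 10
magnification: 1000          # 1 cm printed : 10 um original
solidify_thickness: 1        # mm; stable FDM wall
splits:
  - {part: cell_surface}
fits:
  - {host: cell_surface, insert: nucleus, clearance: 0.3}
print:
  layer_height: 0.2
  infill_percent: 10
  infill_pattern: triangular
  supports: true
seed: 1
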