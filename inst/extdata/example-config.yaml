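# Example run configuration: all omitted fields fall back to the study
# defaults (0.9 A, 20 mm / 1 mm discs at 45 x 22 mm pitch, 15 mm holes in a
# 45 mm quincunx, burr-hole conductivity uncertain on [0.465, 1.654] S/m).
voxel_mm: 3
sr_variant: over_tumor
layout:
  family: circumferential
  parameters: [0, 15, 30, 45, 60, 75, 90, 105, 120, 135, 150, 165]
seed: 1
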