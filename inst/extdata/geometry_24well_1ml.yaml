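# As geometry_24well_2ml.yaml but with 1 mL of exposure medium.
plate_format: "24"
well_diameter_mm: 15.6
total_well_volume_ml: 3.3
medium_volume_ml: 1.0
biota:
  kind: cell_monolayer
  count: 300000
  diameter_um: 15
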