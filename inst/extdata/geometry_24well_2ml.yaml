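# Assumed manufacturer-typical dimensions for a 24-well polystyrene plate
# well with 2 mL working volume; override with measured dimensions where
# available.
plate_format: "24"
well_diameter_mm: 15.6
total_well_volume_ml: 3.3
medium_volume_ml: 2.0
biota:
  kind: cell_monolayer
  count: 300000
  diameter_um: 15
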