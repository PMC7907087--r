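# Starting values for loss-model calibration (not a fitted set):
# p1 midpoint, p2 volatility weight, p3 volatility threshold offset,
# p4 slope.
cover: custom
p1: 4.0
p2: 1.0
p3: 6.0
p4: -1.0
provenance: starting values
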