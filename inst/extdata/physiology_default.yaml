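plasma_volume: 5200.0
renal_clearance: 20.0
li_per_mg: 0.02666666666666667
compartments:
  brain:
    volume: 1450.0
    flow: 700.0
    partition: 1.5
  thyroid:
    volume: 13.0
    flow: 60.0
    partition: 1.5
  bone:
    volume: 7273.0
    flow: 272.0
    partition: 1.5
  gi_tract:
    volume: 1650.0
    flow: 1100.0
    partition: 1.0
  kidney:
    volume: 280.0
    flow: 1240.0
    partition: 1.0
  uterus:
    volume: 1000.0
    flow: 475.0
    partition: 0.40000000000000002
  fetus:
    volume: 150.0
    flow: 300.0
    partition: 0.80000000000000004
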