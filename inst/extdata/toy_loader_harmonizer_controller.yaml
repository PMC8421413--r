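format: aaflux-model/1
name: loader_harmonizer_controller
units:
  km: uM
  vmax: nmol/mg protein/min
  volume: fL
  cells_per_ug: cells/ug protein
  ion_km: mM
  rate: 1/min
volume_fl: 2000.0
cells_per_ug: 7000.0
ions:
  na_ext: 140.0
  na_cyt: 14.0
  k_ext: 5.4
  k_cyt: 140.0
  ph_ext: 7.4
  ph_cyt: 7.2
  potential: -0.06
  temperature: 310.0
conversions: []
depletions: []
transporters:
- name: LOAD
  mechanism: symporter
  z: 1
  vmax: 18.721239
  couplings:
  - ion: Na
    mode: cotransport
    count: 1
    hill_n: 1
    km_ion: 30.0
    applies_to: ~
  substrates:
    A:
      km_ext: 253.1017326
      km_int: 253.1017326
      estimated: no
- name: HARM
  mechanism: antiporter
  z: 0
  vmax: 41.4570673
  couplings: []
  substrates:
    A:
      km_ext: 100.0
      km_int: 10000.0
      estimated: no
    B:
      km_ext: 100.0
      km_int: 10000.0
      estimated: no
- name: CTRL
  mechanism: symporter_antiporter
  z: 0
  vmax: 48.1641558
  couplings:
  - ion: Na
    mode: cotransport
    count: 1
    hill_n: 1
    km_ion: 30.0
    applies_to: ~
  - ion: H
    mode: antiport
    count: 1
    hill_n: 1
    km_ion: 5.0e-05
    applies_to: ~
  substrates:
    A:
      km_ext: 3000.0
      km_int: 3000.0
      estimated: no
    B:
      km_ext: 3000.0
      km_int: 3000.0
      estimated: no
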