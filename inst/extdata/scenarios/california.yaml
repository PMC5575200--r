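# Seven scenarios for the introduction to California, compared in one
# round and then re-run after excluding scenarios below 0.10 probability.
experiment: california
populations:
  - {name: China, role: native}
  - {name: US_East, role: introduced}
  - {name: US_NW, role: introduced}
  - {name: California, role: introduced}
priors:
  N_China: {dist: uniform, min: 10, max: 10000}
  N_US_East: {dist: uniform, min: 10, max: 10000}
  N_US_NW: {dist: uniform, min: 10, max: 10000}
  N_California: {dist: uniform, min: 10, max: 10000}
  t_ca: {dist: uniform, min: 10, max: 10000}
  t_east: {dist: uniform, min: 10, max: 10000}
  t_nw: {dist: uniform, min: 10, max: 10000}
  t_spread: {dist: uniform, min: 10, max: 10000}
  r_adm: {dist: uniform, min: 0.001, max: 0.999}
conditions:
  - "N_US_East < N_China"
  - "N_US_NW < N_China"
  - "N_California < N_China"
sample_sizes: {China: 158, US_East: 70, US_NW: 25, California: 13}
scenarios:
  - id: 1
    description: separate introduction from China
    events:
      - {time: t_ca, kind: merge, child: California, parent: China}
      - {time: t_east, kind: merge, child: US_East, parent: China}
      - {time: t_nw, kind: merge, child: US_NW, parent: China}
  - id: 2
    description: dispersal from northwestern US
    conditions: ["t_ca < t_nw"]
    events:
      - {time: t_ca, kind: merge, child: California, parent: US_NW}
      - {time: t_east, kind: merge, child: US_East, parent: China}
      - {time: t_nw, kind: merge, child: US_NW, parent: China}
  - id: 3
    description: dispersal from eastern US
    conditions: ["t_ca < t_east"]
    events:
      - {time: t_ca, kind: merge, child: California, parent: US_East}
      - {time: t_east, kind: merge, child: US_East, parent: China}
      - {time: t_nw, kind: merge, child: US_NW, parent: China}
  - id: 4
    description: California first, then spread east
    conditions: ["t_spread < t_ca"]
    events:
      - {time: t_ca, kind: merge, child: California, parent: China}
      - {time: t_spread, kind: merge, child: US_East, parent: California}
      - {time: t_nw, kind: merge, child: US_NW, parent: China}
  - id: 5
    description: mixture of northwestern and eastern US
    conditions: ["t_ca < t_nw", "t_ca < t_east"]
    events:
      - {time: t_ca, kind: admixture, child: California, parent: US_NW, parent_b: US_East, rate: r_adm}
      - {time: t_east, kind: merge, child: US_East, parent: China}
      - {time: t_nw, kind: merge, child: US_NW, parent: China}
  - id: 6
    description: mixture of separate China introduction and eastern US
    conditions: ["t_ca < t_east"]
    events:
      - {time: t_ca, kind: admixture, child: California, parent: China, parent_b: US_East, rate: r_adm}
      - {time: t_east, kind: merge, child: US_East, parent: China}
      - {time: t_nw, kind: merge, child: US_NW, parent: China}
  - id: 7
    description: mixture of separate China introduction and northwestern US
    conditions: ["t_ca < t_nw"]
    events:
      - {time: t_ca, kind: admixture, child: California, parent: China, parent_b: US_NW, rate: r_adm}
      - {time: t_east, kind: merge, child: US_East, parent: China}
      - {time: t_nw, kind: merge, child: US_NW, parent: China}
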