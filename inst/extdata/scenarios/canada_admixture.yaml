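# Did Canada come from China alone, from the US alone, or from a mixture
# of China with the eastern or northwestern US populations?
experiment: canada_admixture
populations:
  - {name: China, role: native}
  - {name: US_East, role: introduced}
  - {name: US_NW, role: introduced}
  - {name: Canada, role: introduced}
priors:
  N_China: {dist: uniform, min: 10, max: 10000}
  N_US_East: {dist: uniform, min: 10, max: 10000}
  N_US_NW: {dist: uniform, min: 10, max: 10000}
  N_Canada: {dist: uniform, min: 10, max: 10000}
  t_can: {dist: uniform, min: 10, max: 10000}
  t_us_east: {dist: uniform, min: 10, max: 10000}
  t_us_nw: {dist: uniform, min: 10, max: 10000}
  r_adm: {dist: uniform, min: 0.001, max: 0.999}
conditions:
  - "N_Canada < N_China"
  - "N_US_East < N_China"
  - "N_US_NW < N_China"
  - "t_can < t_us_east"
  - "t_can < t_us_nw"
sample_sizes: {China: 158, US_East: 70, US_NW: 25, Canada: 51}
scenarios:
  - id: 1
    description: China only source
    events:
      - {time: t_can, kind: merge, child: Canada, parent: China}
      - {time: t_us_east, kind: merge, child: US_East, parent: China}
      - {time: t_us_nw, kind: merge, child: US_NW, parent: China}
  - id: 2
    description: US only source
    events:
      - {time: t_can, kind: merge, child: Canada, parent: US_East}
      - {time: t_us_east, kind: merge, child: US_East, parent: China}
      - {time: t_us_nw, kind: merge, child: US_NW, parent: China}
  - id: 3
    description: China + East US mixture
    events:
      - {time: t_can, kind: admixture, child: Canada, parent: China, parent_b: US_East, rate: r_adm}
      - {time: t_us_east, kind: merge, child: US_East, parent: China}
      - {time: t_us_nw, kind: merge, child: US_NW, parent: China}
  - id: 4
    description: China + Northwest US mixture
    events:
      - {time: t_can, kind: admixture, child: Canada, parent: China, parent_b: US_NW, rate: r_adm}
      - {time: t_us_east, kind: merge, child: US_East, parent: China}
      - {time: t_us_nw, kind: merge, child: US_NW, parent: China}
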