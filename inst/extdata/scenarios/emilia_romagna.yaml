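# Emilia-Romagna (southern Italy population): dispersal from the rest of
# Europe, bridgehead from the eastern US, or separate China introduction?
experiment: emilia_romagna
populations:
  - {name: China, role: native}
  - {name: US_East, role: introduced}
  - {name: Europe_N, role: introduced}
  - {name: Emilia, role: introduced}
priors:
  N_China: {dist: uniform, min: 10, max: 10000}
  N_US_East: {dist: uniform, min: 10, max: 10000}
  N_Europe_N: {dist: uniform, min: 10, max: 10000}
  N_Emilia: {dist: uniform, min: 10, max: 10000}
  t_em: {dist: uniform, min: 10, max: 10000}
  t_eu: {dist: uniform, min: 10, max: 10000}
  t_us: {dist: uniform, min: 10, max: 10000}
conditions:
  - "N_US_East < N_China"
  - "N_Europe_N < N_China"
  - "N_Emilia < N_China"
sample_sizes: {China: 158, US_East: 70, Europe_N: 455, Emilia: 31}
scenarios:
  - id: 1
    description: dispersal from Europe
    conditions: ["t_em < t_eu"]
    events:
      - {time: t_em, kind: merge, child: Emilia, parent: Europe_N}
      - {time: t_eu, kind: merge, child: Europe_N, parent: China}
      - {time: t_us, kind: merge, child: US_East, parent: China}
  - id: 2
    description: bridgehead from US
    conditions: ["t_em < t_us"]
    events:
      - {time: t_em, kind: merge, child: Emilia, parent: US_East}
      - {time: t_eu, kind: merge, child: Europe_N, parent: China}
      - {time: t_us, kind: merge, child: US_East, parent: China}
  - id: 3
    description: separate introduction from China
    events:
      - {time: t_em, kind: merge, child: Emilia, parent: China}
      - {time: t_eu, kind: merge, child: Europe_N, parent: China}
      - {time: t_us, kind: merge, child: US_East, parent: China}
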