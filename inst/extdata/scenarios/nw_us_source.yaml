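# Native source of the northwestern US (Oregon/Washington) introduction.
experiment: nw_us_source
populations:
  - {name: China, role: native}
  - {name: Japan, role: native}
  - {name: Korea, role: native}
  - {name: US_NW, role: introduced}
priors:
  N_China: {dist: uniform, min: 10, max: 10000}
  N_Japan: {dist: uniform, min: 10, max: 10000}
  N_Korea: {dist: uniform, min: 10, max: 10000}
  N_US_NW: {dist: uniform, min: 10, max: 10000}
  t_intro: {dist: uniform, min: 10, max: 10000}
  t_nat1: {dist: uniform, min: 10, max: 10000}
  t_nat2: {dist: uniform, min: 10, max: 10000}
conditions:
  - "N_US_NW < min(N_China, N_Japan, N_Korea)"
  - "t_intro < t_nat1"
  - "t_nat1 < t_nat2"
sample_sizes: {China: 158, Japan: 44, Korea: 12, US_NW: 25}
scenarios:
  - id: 1
    description: China source
    events:
      - {time: t_intro, kind: merge, child: US_NW, parent: China}
      - {time: t_nat1, kind: merge, child: Korea, parent: Japan}
      - {time: t_nat2, kind: merge, child: Japan, parent: China}
  - id: 2
    description: Japan source
    events:
      - {time: t_intro, kind: merge, child: US_NW, parent: Japan}
      - {time: t_nat1, kind: merge, child: Korea, parent: Japan}
      - {time: t_nat2, kind: merge, child: Japan, parent: China}
  - id: 3
    description: Korea source
    events:
      - {time: t_intro, kind: merge, child: US_NW, parent: Korea}
      - {time: t_nat1, kind: merge, child: Korea, parent: Japan}
      - {time: t_nat2, kind: merge, child: Japan, parent: China}
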