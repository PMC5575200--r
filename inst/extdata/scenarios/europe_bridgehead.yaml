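# Was early Europe seeded directly from China or via a bridgehead from the
# eastern or western US populations?
experiment: europe_bridgehead
populations:
  - {name: China, role: native}
  - {name: US_East, role: introduced}
  - {name: US_West, role: introduced}
  - {name: Europe, role: introduced}
priors:
  N_China: {dist: uniform, min: 10, max: 10000}
  N_US_East: {dist: uniform, min: 10, max: 10000}
  N_US_West: {dist: uniform, min: 10, max: 10000}
  N_Europe: {dist: uniform, min: 10, max: 10000}
  t_eu: {dist: uniform, min: 10, max: 10000}
  t_us_east: {dist: uniform, min: 10, max: 10000}
  t_us_west: {dist: uniform, min: 10, max: 10000}
conditions:
  - "N_US_East < N_China"
  - "N_US_West < N_China"
  - "N_Europe < N_China"
sample_sizes: {China: 158, US_East: 70, US_West: 38, Europe: 486}
scenarios:
  - id: 1
    description: China source
    events:
      - {time: t_eu, kind: merge, child: Europe, parent: China}
      - {time: t_us_east, kind: merge, child: US_East, parent: China}
      - {time: t_us_west, kind: merge, child: US_West, parent: China}
  - id: 2
    description: bridgehead from eastern US
    conditions: ["t_eu < t_us_east"]
    events:
      - {time: t_eu, kind: merge, child: Europe, parent: US_East}
      - {time: t_us_east, kind: merge, child: US_East, parent: China}
      - {time: t_us_west, kind: merge, child: US_West, parent: China}
  - id: 3
    description: bridgehead from western US
    conditions: ["t_eu < t_us_west"]
    events:
      - {time: t_eu, kind: merge, child: Europe, parent: US_West}
      - {time: t_us_east, kind: merge, child: US_East, parent: China}
      - {time: t_us_west, kind: merge, child: US_West, parent: China}
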