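# Introduction history of Greece and Hungary: Greece from China only,
# Greece a mixture of Hungary and China, or a China introduction to
# Greece that then spread to Hungary.
experiment: greece_hungary
populations:
  - {name: China, role: native}
  - {name: Hungary, role: introduced}
  - {name: Greece, role: introduced}
priors:
  N_China: {dist: uniform, min: 10, max: 10000}
  N_Hungary: {dist: uniform, min: 10, max: 10000}
  N_Greece: {dist: uniform, min: 10, max: 10000}
  t_gr: {dist: uniform, min: 10, max: 10000}
  t_hu: {dist: uniform, min: 10, max: 10000}
  r_adm: {dist: uniform, min: 0.001, max: 0.999}
conditions:
  - "N_Hungary < N_China"
  - "N_Greece < N_China"
sample_sizes: {China: 158, Hungary: 84, Greece: 57}
scenarios:
  - id: 1
    description: Greece from China only
    events:
      - {time: t_gr, kind: merge, child: Greece, parent: China}
      - {time: t_hu, kind: merge, child: Hungary, parent: China}
  - id: 2
    description: mixture from Hungary and China
    conditions: ["t_gr < t_hu"]
    events:
      - {time: t_gr, kind: admixture, child: Greece, parent: China, parent_b: Hungary, rate: r_adm}
      - {time: t_hu, kind: merge, child: Hungary, parent: China}
  - id: 3
    description: China source that spread to Hungary
    conditions: ["t_hu < t_gr"]
    events:
      - {time: t_hu, kind: merge, child: Hungary, parent: Greece}
      - {time: t_gr, kind: merge, child: Greece, parent: China}
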