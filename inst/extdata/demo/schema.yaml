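target_types:
- ncRNA
- disease
node_types:
  ncRNA:
    attributes:
      expression: numeric
      family: categorical
  disease:
    attributes:
      severity: numeric
      category: categorical
  gene:
    attributes:
      activity: numeric
      pathway: categorical
edge_types:
- name: ncRNA-gene
  from: ncRNA
  to: gene
- name: gene-disease
  from: gene
  to: disease
- name: ncRNA-disease
  from: ncRNA
  to: disease
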