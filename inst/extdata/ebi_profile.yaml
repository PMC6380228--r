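profile: EBI
attributes:
- name: Organism
  class: ontology_term
  ontology: NCBITaxon
- name: Material
  class: ontology_term
  ontology: ANY
- name: Sex
  class: value_set
  value_set: sex
value_sets:
  sex:
  - male
  - female
  - pooled male and female
  - neuter
  - hermaphrodite
  - intersex
  - not determined
  - missing
  - not applicable
  - not collected
packages: []

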