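name: PPZ
steps:
- product: PER
  precursor: ~
  required_genes:
  - ppzA-A1
  - ppzA-T1
  - ppzA-C
  - ppzA-A2
  - ppzA-M
  - ppzA-T2
  - ppzA-R
- product: PPZ-dione
  precursor: ~
  required_genes:
  - ppzA-A1
  - ppzA-T1
  - ppzA-C
  - ppzA-A2
  - ppzA-M
  - ppzA-T2
  - ppzA-dR
terminal_products:
- PER
- PPZ-dione
toxic_products: []
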