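name: IDT
steps:
- product: PAS
  precursor: ~
  required_genes:
  - idtG
  - idtB
  - idtM
  - idtC
  - idtS
- product: PAX
  precursor: PAS
  required_genes:
  - idtP
  - idtQ
- product: TDK
  precursor: PAX
  required_genes:
  - idtF
  - idtK
- product: LTM-B
  precursor: TDK
  required_genes:
  - idtE
  - idtJ
terminal_products:
- LTM-B
toxic_products:
- PAS
- PAX
- TDK
- LTM-B
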