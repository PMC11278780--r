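name: EAS
steps:
- product: CC
  precursor: ~
  required_genes:
  - dmaW
  - easF
  - easC
  - easE
- product: D-LC
  precursor: CC
  required_genes:
  - easD
  - easA
  - easG
  - cloA
- product: ERV
  precursor: D-LC
  required_genes:
  - lpsA
  - lpsB
  - easH
- product: EN
  precursor: D-LC
  required_genes:
  - lpsC
- product: LAH
  precursor: EN
  required_genes:
  - easO
  - easP
terminal_products:
- ERV
- LAH
toxic_products:
- CC
- D-LC
- ERV
- EN
- LAH
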