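name: LOL
steps:
- product: AcAP
  precursor: ~
  required_genes:
  - lolC
  - lolF
  - lolD
  - lolT
  - lolU
- product: NFL
  precursor: AcAP
  required_genes:
  - lolA
  - lolO
  - lolP
  - lolE
  - lolN
  - lolM
- product: NAL
  precursor: AcAP
  required_genes:
  - lolA
  - lolO
  - lolP
  - lolE
  - lolN
  - lolM
terminal_products:
- NFL
- NAL
toxic_products: []
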