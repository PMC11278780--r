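{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Pathway model",
  "description": "A gene-gated dependency model of an alkaloid biosynthesis pathway. Each step produces one metabolite when all required_genes are present and the precursor (if any) is itself producible. The precursor graph must be acyclic.",
  "type": "object",
  "required": ["name", "steps"],
  "properties": {
    "name": { "type": "string", "minLength": 1 },
    "steps": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["product", "required_genes"],
        "properties": {
          "product": { "type": "string", "minLength": 1 },
          "precursor": { "type": ["string", "null"] },
          "required_genes": {
            "type": "array",
            "items": { "type": "string", "minLength": 1 }
          },
          "notes": { "type": "string" }
        }
      }
    },
    "terminal_products": { "type": "array", "items": { "type": "string" } },
    "toxic_products": { "type": "array", "items": { "type": "string" } }
  }
}
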