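{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Chemotype result",
  "description": "One strain's inference result as emitted by write_results_json (the JSON report is an object keyed by strain id, each value matching this schema).",
  "type": "object",
  "required": ["strain_id", "producible", "ppz_allele", "mating_type",
               "pattern_codes", "chem_type", "safety_category"],
  "properties": {
    "strain_id": { "type": "string" },
    "producible": { "type": "array", "items": { "type": "string" } },
    "producible_by_model": {
      "type": "object",
      "additionalProperties": { "type": "array", "items": { "type": "string" } }
    },
    "terminal_products": { "type": "array", "items": { "type": "string" } },
    "ppz_allele": { "enum": ["ppzA-1", "ppzA-2", "none", "conflict"] },
    "mating_type": { "enum": ["A", "B", "undetermined", "conflict"] },
    "pattern_codes": {
      "type": "object",
      "additionalProperties": { "type": "string", "pattern": "^[A-Z]$" }
    },
    "chem_type": { "enum": ["1", "2", "3", "4", "unclassified"] },
    "safety_category": { "enum": ["I", "II"] },
    "warnings": { "type": "array", "items": { "type": "string" } }
  }
}
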