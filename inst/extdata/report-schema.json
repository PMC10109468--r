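{
  "flow": {
    "required": {
      "report": "string",
      "n_images": "integer",
      "n_agreement": "integer",
      "n_agreement_no_fossil": "integer",
      "n_agreement_fossil": "integer",
      "n_fossil_pollen_spore": "integer",
      "n_fossil_unknown": "integer",
      "n_disputed": "integer",
      "n_no_agreement": "integer",
      "n_review_queue": "integer",
      "n_pending": "integer"
    }
  },
  "census": {
    "required": {
      "report": "string",
      "totals": "object",
      "taxa": "array"
    }
  },
  "performance": {
    "required": {
      "report": "string",
      "recall": "number",
      "n_truth": "integer",
      "n_matched": "integer",
      "n_false": "integer"
    }
  }
}
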