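{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "haplopower run record",
  "type": "object",
  "required": ["command", "version", "timestamp", "parameters", "result"],
  "properties": {
    "command": {
      "type": "string",
      "enum": ["power", "posthoc", "samplesize", "mindetect",
               "calibrate", "fixture"]
    },
    "version": {"type": "string"},
    "timestamp": {"type": "string"},
    "elapsed_s": {"type": "number"},
    "seed": {"type": ["integer", "null"]},
    "parameters": {"type": "object"},
    "result": {"type": "object"}
  }
}
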