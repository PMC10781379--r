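{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "feverwatch event packet",
  "description": "One sensor event, sent as a single newline-delimited UTF-8 JSON line over TCP. Keys are lowercase and serialized in the order id, time, type, payload.",
  "type": "object",
  "properties": {
    "id": {
      "type": "string",
      "description": "Device id: common name + '-' + last four hex digits of the MAC address",
      "pattern": "^.+-[0-9A-F]{4}$"
    },
    "time": {
      "type": "integer",
      "minimum": 0,
      "description": "Event time, epoch seconds (UTC)"
    },
    "type": {
      "type": "string",
      "enum": ["thermal", "cough"]
    },
    "temperature": {
      "type": "number",
      "description": "Corrected patient temperature in degC; present iff type is 'thermal', and only emitted when strictly above the 38 degC fever threshold"
    },
    "audio": {
      "type": "string",
      "description": "Base64-encoded WAV bytes (16-bit PCM mono 16 kHz); present iff type is 'cough'"
    }
  },
  "required": ["id", "time", "type"],
  "oneOf": [
    {
      "properties": {"type": {"const": "thermal"}},
      "required": ["temperature"],
      "not": {"required": ["audio"]}
    },
    {
      "properties": {"type": {"const": "cough"}},
      "required": ["audio"],
      "not": {"required": ["temperature"]}
    }
  ],
  "additionalProperties": false
}
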