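{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "fragmatch annotation document",
  "type": "object",
  "required": ["format_version", "peptides", "precursor", "settings",
               "peaks", "fragments", "matches"],
  "properties": {
    "format_version": {"type": "string", "enum": ["1.0"]},
    "peptides": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["sequence", "mods"],
        "properties": {
          "sequence": {"type": "string"},
          "mods": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["position", "name", "mass_delta"],
              "properties": {
                "position": {"type": "integer"},
                "name": {"type": "string"},
                "mass_delta": {"type": "number"}
              }
            }
          },
          "link_position": {"type": ["integer", "null"]}
        }
      }
    },
    "crosslinker_mass": {"type": ["number", "null"]},
    "precursor": {
      "type": "object",
      "required": ["charge"],
      "properties": {
        "charge": {"type": "integer"},
        "mz": {"type": ["number", "null"]}
      }
    },
    "settings": {
      "type": "object",
      "required": ["tolerance", "ion_types", "max_fragment_charge",
                   "losses_enabled", "z_radical"],
      "properties": {
        "tolerance": {
          "type": "object",
          "required": ["value", "unit"],
          "properties": {
            "value": {"type": "number"},
            "unit": {"type": "string", "enum": ["ppm", "da"]}
          }
        },
        "ion_types": {"type": "array", "items": {"type": "string",
          "enum": ["precursor", "b", "c", "y", "z"]}},
        "max_fragment_charge": {"type": "integer"},
        "losses_enabled": {"type": "boolean"},
        "z_radical": {"type": "boolean"}
      }
    },
    "peaks": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["mz", "intensity"],
        "properties": {
          "mz": {"type": "number"},
          "intensity": {"type": "number"}
        }
      }
    },
    "fragments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["label", "series", "index", "peptide_id", "charge",
                     "neutral_mass", "mz", "loss", "contains_link"],
        "properties": {
          "label": {"type": "string"},
          "series": {"type": "string",
            "enum": ["precursor", "b", "c", "y", "z"]},
          "index": {"type": "integer"},
          "peptide_id": {"type": "string", "enum": ["alpha", "beta"]},
          "charge": {"type": "integer"},
          "neutral_mass": {"type": "number"},
          "mz": {"type": "number"},
          "loss": {"type": "string", "enum": ["none", "H2O", "NH3"]},
          "contains_link": {"type": "boolean"}
        }
      }
    },
    "matches": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["peak_index", "fragment_index", "isotope_peak",
                     "error_Da", "error_ppm"],
        "properties": {
          "peak_index": {"type": "integer"},
          "fragment_index": {"type": "integer"},
          "isotope_peak": {"type": "integer"},
          "error_Da": {"type": "number"},
          "error_ppm": {"type": "number"}
        }
      }
    }
  }
}
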