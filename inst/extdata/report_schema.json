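{
  "type": "object",
  "required": ["seed", "config_hash", "abundance_summary", "monthly",
               "harmonics", "lags", "spectra", "network", "events", "sem"],
  "properties": {
    "seed": {"type": "number"},
    "config_hash": {"type": "string"},
    "abundance_summary": {
      "type": "object",
      "required": ["mean", "sd", "min", "max", "n_samples"],
      "properties": {
        "mean": {"type": "number"},
        "sd": {"type": "number"},
        "min": {"type": "number"},
        "max": {"type": "number"},
        "n_samples": {"type": "number"},
        "n_measured": {"type": "number"}
      }
    },
    "monthly": {"type": "object"},
    "harmonics": {
      "type": "object",
      "required": ["abundance", "local_pm10", "desert_pm10"],
      "properties": {
        "abundance": {
          "type": "object",
          "required": ["a", "b", "c", "amplitude", "phase_rad", "r2", "p", "n"]
        },
        "local_pm10": {
          "type": "object",
          "required": ["a", "b", "c", "amplitude", "phase_rad", "r2", "p", "n"]
        },
        "desert_pm10": {
          "type": "object",
          "required": ["a", "b", "c", "amplitude", "phase_rad", "r2", "p", "n"]
        }
      }
    },
    "lags": {
      "type": "object",
      "required": ["abundance_behind_desert", "local_behind_desert",
                   "abundance_behind_local"],
      "properties": {
        "abundance_behind_desert": {"type": "number"},
        "local_behind_desert": {"type": "number"},
        "abundance_behind_local": {"type": "number"}
      }
    },
    "spectra": {"type": "object"},
    "network": {
      "type": "object",
      "required": ["n_nodes", "n_edges", "modules", "focal",
                   "focal_same_module"],
      "properties": {
        "n_nodes": {"type": "number"},
        "n_edges": {"type": "number"},
        "modules": {"type": "object"},
        "focal_same_module": {"type": "boolean"}
      }
    },
    "events": {
      "type": "object",
      "required": ["n_official", "n_spikes"],
      "properties": {
        "n_official": {"type": "number"},
        "n_spikes": {"type": "number"}
      }
    },
    "sem": {
      "type": "object",
      "required": ["standardized", "chi2", "df", "n", "indices"],
      "properties": {
        "chi2": {"type": "number"},
        "df": {"type": "number"},
        "n": {"type": "number"},
        "indices": {
          "type": "object",
          "required": ["tli", "rmsea", "srmr"],
          "properties": {
            "tli": {"type": "number"},
            "rmsea": {"type": "number"},
            "srmr": {"type": "number"}
          }
        }
      }
    }
  }
}
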