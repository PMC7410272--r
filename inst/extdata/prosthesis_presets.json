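{
  "_comment": "Mass-distribution metrics of representative commercial transhumeral prosthesis components, one preset per terminal-device class. Forearm mass includes the integrated elbow components. COM offsets (fraction of segment length from the proximal end) are defaults, proximal of mid-segment.",
  "version": 1,
  "presets": {
    "body_powered": {
      "elbow_width_m": 0.0635,
      "forearm_mass_kg": 0.555,
      "wrist_width_m": 0.0381,
      "hand_mass_kg": 0.027,
      "hand_length_m": 0.1016,
      "forearm_com_offset": 0.45,
      "hand_com_offset": 0.45
    },
    "myoelectric_hook": {
      "elbow_width_m": 0.0762,
      "forearm_mass_kg": 1.013,
      "wrist_width_m": 0.054,
      "hand_mass_kg": 0.416,
      "hand_length_m": 0.1524,
      "forearm_com_offset": 0.45,
      "hand_com_offset": 0.45
    },
    "myoelectric_hand": {
      "elbow_width_m": 0.0825,
      "forearm_mass_kg": 1.04,
      "wrist_width_m": 0.0635,
      "hand_mass_kg": 0.5,
      "hand_length_m": 0.2159,
      "forearm_com_offset": 0.45,
      "hand_com_offset": 0.45
    },
    "advanced": {
      "elbow_width_m": 0.0773,
      "forearm_mass_kg": 1.875,
      "wrist_width_m": 0.0635,
      "hand_mass_kg": 1.525,
      "hand_length_m": 0.195,
      "forearm_com_offset": 0.45,
      "hand_com_offset": 0.45
    }
  }
}
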