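{
  "_comment": "Published time-zero cadaveric yield / ultimate failure thresholds of the bone-implant interface of transhumeral percutaneous osseointegrated endoprostheses. Moments in N.m, forces in N. 'level' refers to the anatomical test counterpart: proximal (30% amputation) or distal (65%); 'any' aggregates both. 'screws' is the bicortical stabilizing-screw condition. Rows with null yields report only ultimate failure.",
  "version": 1,
  "envelopes": [
    {
      "modality": "axial", "level": "any", "screws": "unspecified",
      "yield_lo": 784.2, "yield_hi": 1818.1,
      "ultimate_lo": 1325.1, "ultimate_hi": 5120.3,
      "source": "porous-coated transhumeral OI endoprosthesis, cadaveric time-zero"
    },
    {
      "modality": "bending", "level": "any", "screws": "unspecified",
      "yield_lo": 1.7, "yield_hi": 2.3,
      "ultimate_lo": 70.3, "ultimate_hi": 119.4,
      "source": "porous-coated transhumeral OI endoprosthesis, cadaveric time-zero"
    },
    {
      "modality": "torsion", "level": "any", "screws": "unspecified",
      "yield_lo": 4.5, "yield_hi": 10.2,
      "ultimate_lo": 6.0, "ultimate_hi": 42.2,
      "source": "porous-coated transhumeral OI endoprosthesis, cadaveric time-zero"
    },
    {
      "modality": "torsion", "level": "any", "screws": "without",
      "yield_lo": 4.5, "yield_hi": 4.5,
      "ultimate_lo": 6.0, "ultimate_hi": 12.7,
      "source": "same implant, without stabilizing screws"
    },
    {
      "modality": "torsion", "level": "any", "screws": "with",
      "yield_lo": 10.2, "yield_hi": 10.2,
      "ultimate_lo": 42.2, "ultimate_hi": 42.2,
      "source": "same implant, with stabilizing screws (synthetic reconstruction: upper ends of the published aggregate ranges attributed to the screw-stabilized condition)"
    },
    {
      "modality": "torsion", "level": "proximal", "screws": "without",
      "yield_lo": 4.5, "yield_hi": 4.5,
      "ultimate_lo": 6.0, "ultimate_hi": 6.0,
      "source": "same implant, without stabilizing screws, proximal level"
    },
    {
      "modality": "bending", "level": "any", "screws": "unspecified",
      "yield_lo": null, "yield_hi": null,
      "ultimate_lo": 36.7, "ultimate_hi": 36.7,
      "source": "cementless intramedullary stem (MUTARS), ultimate 36.7 +/- 11.0 N.m"
    }
  ]
}
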