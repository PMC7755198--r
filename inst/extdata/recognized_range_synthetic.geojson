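{
  "type": "Feature",
  "properties": {
    "name": "recognized range (synthetic, coarse)",
    "note": "Deliberately simplified stand-in for the most recognized distribution of Phoenicopterus ruber: Caribbean basin, Yucatan Peninsula and northern South American coast, plus the Galapagos Islands. For examples and tests only."
  },
  "geometry": {
    "type": "MultiPolygon",
    "coordinates": [
      [[[-92.0, 8.0], [-58.0, 8.0], [-58.0, 28.0], [-92.0, 28.0], [-92.0, 8.0]]],
      [[[-92.5, -1.6], [-88.8, -1.6], [-88.8, 1.0], [-92.5, 1.0], [-92.5, -1.6]]]
    ]
  }
}
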