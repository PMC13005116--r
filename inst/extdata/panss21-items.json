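{
  "codes": ["P1", "P2", "P3", "P6", "P7", "N1", "N2", "N3", "N4", "N5", "N6", "N7", "G5", "G7", "G8", "G9", "G10", "G13", "G14", "G15", "G16"],
  "domains": {
    "P1": "Positive",
    "P2": "Cognitive/Disorganized",
    "P3": "Positive",
    "P6": "Positive",
    "P7": "Excited/Aggressive",
    "N1": "Negative",
    "N2": "Negative",
    "N3": "Negative",
    "N4": "Negative",
    "N5": "Cognitive/Disorganized",
    "N6": "Negative",
    "N7": "Cognitive/Disorganized",
    "G5": "Cognitive/Disorganized",
    "G7": "Cognitive/Disorganized",
    "G8": "Excited/Aggressive",
    "G9": "Positive",
    "G10": "Cognitive/Disorganized",
    "G13": "Cognitive/Disorganized",
    "G14": "Excited/Aggressive",
    "G15": "Cognitive/Disorganized",
    "G16": "Negative"
  },
  "remissionItems": ["P1", "P2", "P3", "N1", "N4", "N6", "G5", "G9"]
}
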