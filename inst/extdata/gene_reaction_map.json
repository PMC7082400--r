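{
  "Sox": {
    "genes": ["sox-1", "sox-2"],
    "reactions": ["F1.sox", "T3.eq4f", "T3.eq4r"],
    "compartment": "periplasm"
  },
  "TetH": {
    "genes": "tetH",
    "reactions": ["T3.eq6", "T3.eq10", "T3.eq5"],
    "compartment": "periplasm",
    "note": "T3.eq5 assignment is a candidate (possible reverse activity); DoxD or an unknown protein may catalyse it instead"
  },
  "DoxD": {
    "genes": "doxD",
    "reactions": "T3.eq5",
    "compartment": "membrane"
  },
  "Sqr": {
    "genes": "sqr",
    "reactions": "F1.sqr",
    "compartment": "membrane"
  },
  "Sdo": {
    "genes": ["sdo-1", "sdo-2", "sdo-3"],
    "reactions": "T3.eq2",
    "compartment": "cytoplasm"
  },
  "Sor": {
    "genes": "sor",
    "reactions": "T3.eq2",
    "compartment": "cytoplasm"
  },
  "Rhd": {
    "genes": ["rhd-1", "rhd-2"],
    "reactions": ["T3.eq4f", "T3.eq4r"],
    "compartment": "cytoplasm"
  },
  "Hdr": {
    "genes": ["hdrA-1", "hdrA-2", "hdrA-3", "hdrB", "hdrC"],
    "reactions": "T3.eq2",
    "compartment": "cytoplasm"
  },
  "Aps": {
    "genes": "aps",
    "reactions": "T3.eq9",
    "compartment": "cytoplasm"
  },
  "Paps": {
    "genes": "paps",
    "reactions": "T3.eq9",
    "compartment": "cytoplasm"
  }
}
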