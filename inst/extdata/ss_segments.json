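{
  "_comment": "Editable six-helix-bundle segment annotations (inclusive author residue ranges). The IFI16 entry is an approximate annotation following the canonical pyrin-domain topology (short helix 3; proline-shifted h5/h6 boundary) and can be replaced by a curated one.",
  "IFI16": {
    "h1": [4, 14],
    "loop_h1h2": [15, 17],
    "h2": [18, 29],
    "loop_h2h3": [30, 41],
    "h3": [42, 46],
    "loop_h3h4": [47, 49],
    "h4": [50, 59],
    "loop_h4h5": [60, 62],
    "h5": [63, 70],
    "loop_h5h6": [71, 75],
    "h6": [76, 90]
  }
}
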