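{
  "comment": "Synthetic reduced haplogroup tree for the bundled HVRI reference segment. Labels follow standard mtDNA nomenclature but the defining variants are synthetic: they are chosen against the package's synthetic HVRI reference, not against the rCRS.",
  "nodes": {
    "rCRS":    {"parent": null,    "variants": []},
    "HV":      {"parent": "rCRS",  "variants": ["16263C"]},
    "HV0":     {"parent": "HV",    "variants": ["16298C"]},
    "H":       {"parent": "HV",    "variants": ["16354C"]},
    "H1":      {"parent": "H",     "variants": ["16162A"]},
    "H1cf":    {"parent": "H1",    "variants": ["16260C"]},
    "H4":      {"parent": "H",     "variants": ["16240G"]},
    "H4a1e":   {"parent": "H4",    "variants": ["16092C"]},
    "JT":      {"parent": "rCRS",  "variants": ["16126T"]},
    "J":       {"parent": "JT",    "variants": ["16069T"]},
    "T":       {"parent": "JT",    "variants": ["16294C"]},
    "T2":      {"parent": "T",     "variants": ["16304C"]},
    "T2c1":    {"parent": "T2",    "variants": ["16292T"]},
    "U":       {"parent": "rCRS",  "variants": ["16249T"]},
    "K":       {"parent": "U",     "variants": ["16224C"]},
    "U5":      {"parent": "U",     "variants": ["16270C"]},
    "U6":      {"parent": "U",     "variants": ["16172C", "16219G"]},
    "U6a":     {"parent": "U6",    "variants": ["16278T"]},
    "U6b":     {"parent": "U6",    "variants": ["16163G"]},
    "U6b1a":   {"parent": "U6b",   "variants": ["16293G", "@16219"]},
    "U6c":     {"parent": "U6",    "variants": ["16169T"]},
    "U7":      {"parent": "U",     "variants": ["16318T"]},
    "L1b":     {"parent": "rCRS",  "variants": ["16187T", "16189C"]},
    "L3":      {"parent": "rCRS",  "variants": ["16223T"]},
    "L3b":     {"parent": "L3",    "variants": ["16124C"]},
    "L3b1a":   {"parent": "L3b",   "variants": ["16362C"]},
    "L3b1a12": {"parent": "L3b1a", "variants": ["16148T"]},
    "M1":      {"parent": "L3",    "variants": ["16129A"]},
    "W1e1":    {"parent": "rCRS",  "variants": ["16286T", "16320T"]},
    "X3a":     {"parent": "rCRS",  "variants": ["16093C", "16255A"]}
  }
}
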