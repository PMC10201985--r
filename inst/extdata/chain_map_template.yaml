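# Chain map template: protein (gene) name -> chain id in the coordinate file
# and encoding compartment. Complete the chain ids from the PDB entry
# metadata of the deposited ribosome before running on the real structure;
# the deposition's own chain naming, not this package, is authoritative.
# `offset` (optional, default 0) is added to sequence-derived residue
# numbers to reach the structure's author numbering.
rps11: {chain: "FILL_ME", compartment: plastid, offset: 0}
rps21: {chain: "FILL_ME", compartment: nuclear, offset: 0}
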