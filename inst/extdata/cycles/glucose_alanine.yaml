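name: glucose_alanine
legs:
  - compartment: muscle
    role: producer
    metabolites: [Ala]
    enzymes: [Gpt2]
    transporters: [Asct1, Asct2]
    flow: alanine release into blood
  - compartment: blood
    role: carrier
    metabolites: [Ala, Glucose]
    flow: circulation
  - compartment: liver
    role: consumer
    metabolites: [Ala]
    enzymes: [Gpt, Gpt2]
    transporters: [Asct1, Asct2]
    flow: alanine uptake, conversion to pyruvate
  - compartment: liver
    role: producer
    metabolites: [Glucose]
    flow: gluconeogenic glucose release
  - compartment: muscle
    role: consumer
    metabolites: [Glucose, G6P, F6P, "F1,6P", PEP]
    transporters: [Slc2a4]
    flow: glucose uptake into glycolysis
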