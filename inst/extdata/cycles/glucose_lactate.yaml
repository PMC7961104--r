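name: glucose_lactate
legs:
  - compartment: muscle
    role: producer
    metabolites: [Lactate]
    enzymes: [Ldha]
    transporters: [Slc16a1]
    flow: lactate release into blood
  - compartment: blood
    role: carrier
    metabolites: [Lactate, Glucose]
    flow: circulation
  - compartment: liver
    role: consumer
    metabolites: [Lactate]
    enzymes: [Ldha]
    transporters: [Slc16a1]
    flow: lactate uptake, conversion to pyruvate
  - compartment: liver
    role: producer
    metabolites: [Glucose]
    flow: gluconeogenic glucose release
  - compartment: muscle
    role: consumer
    metabolites: [Glucose]
    transporters: [Slc2a4]
    flow: glucose uptake
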