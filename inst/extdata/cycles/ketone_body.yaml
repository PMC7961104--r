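name: ketone_body
legs:
  - compartment: liver
    role: producer
    metabolites: [Acetoacetate, 3-OH-butyrate]
    enzymes: [Hmgcs2, Hmgcl, Bdh1]
    transporters: [Slc16a6]
    flow: ketone body synthesis from fatty acid degradation and release
  - compartment: blood
    role: carrier
    metabolites: [Acetoacetate, 3-OH-butyrate]
    flow: circulation
  - compartment: muscle
    role: consumer
    metabolites: [Acetoacetate, 3-OH-butyrate]
    enzymes: [Bdh1]
    transporters: [Slc16a7]
    flow: ketone body uptake and oxidation
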