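# Baseline biomass macromolecule mass fractions (g/gDW) and growth-associated
# maintenance (GAM, mmol ATP/gDW) per broad organism class. These are
# literature-typical starting points and must be reviewed/curated for the
# organism being modelled.
gram_negative:
  fractions:
    protein: 0.55
    rna: 0.20
    dna: 0.03
    lipid: 0.09
    carbohydrate: 0.06
    cofactor: 0.07
  gam: 40
gram_positive:
  fractions:
    protein: 0.52
    rna: 0.16
    dna: 0.03
    lipid: 0.08
    carbohydrate: 0.15
    cofactor: 0.06
  gam: 40
fungus:
  fractions:
    protein: 0.45
    rna: 0.08
    dna: 0.02
    lipid: 0.12
    carbohydrate: 0.28
    cofactor: 0.05
  gam: 60
plant:
  fractions:
    protein: 0.30
    rna: 0.05
    dna: 0.02
    lipid: 0.10
    carbohydrate: 0.48
    cofactor: 0.05
  gam: 30
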