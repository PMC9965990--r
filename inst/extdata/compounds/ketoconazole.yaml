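# Ketoconazole (parent) model parameters.
# Kinetic constants in umol/L (K_M, K_i) and 1/min (k_cat); permeabilities
# in cm/min.  The CYP3A4 and P-gp K_M values are surrogated by the
# corresponding autoinhibition K_i values.  Literature (non-default) values
# are carried under metadata.
name: ketoconazole
MW: 531.43
pKa:
  - {value: 2.94, type: base}
  - {value: 6.51, type: base}
solubility:
  - {pH: 1.2, mg_per_L: 2.03e+04}
  - {pH: 3.0, mg_per_L: 4.30e+04}
  - {pH: 6.8, mg_per_L: 7.00}
  - {pH: 7.0, mg_per_L: 5.40}
  - {pH: 7.5, mg_per_L: 6.00}
logP: 2.52
fu: 0.01
blood_plasma_ratio: 0.62
partition_method: Berezhkovskiy
permeability_method: PKSimStandard
intestinal_permeability:
  fasted: 1.56e-5
  fed: 9.95e-6
GFR_fraction: 1.0
EHC_continuous_fraction: 1.0
plasma_restricted: false
processes:
  - {protein: AADAC,  kind: MichaelisMenten, K_M: 1.88,  k_cat: 0.87, product: m1}
  - {protein: CYP3A4, kind: MichaelisMenten, K_M: 0.008, k_cat: 0.10, product: sink}
  - {protein: UGT1A4, kind: MichaelisMenten, K_M: 7.00,  k_cat: 0.31, product: sink}
  - {protein: P-gp,   kind: ActiveEffluxMM,  K_M: 0.035, k_cat: 0.33, product: sink}
inhibitions:
  - {target_protein: CYP3A4, K_i: 0.008}
  - {target_protein: P-gp,   K_i: 0.035}
metadata:
  logP_literature: 2.73
  GET_fasted_min: 15
  GET_fed_min: 45
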