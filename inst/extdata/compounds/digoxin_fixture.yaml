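# SYNTHETIC victim-drug fixture: simplified whole-body surrogate for
# digoxin (P-gp substrate, renally cleared, no CYP3A4 metabolism).  Not a
# published victim PBPK model.
name: digoxin
MW: 780.94
pKa: []
solubility:
  - {pH: 6.5, mg_per_L: 65.0}
logP: 1.26
fu: 0.71
partition_method: Berezhkovskiy
permeability_method: PKSimStandard
intestinal_permeability:
  fasted: 8.0e-5
  fed: 8.0e-5
GFR_fraction: 1.0
EHC_continuous_fraction: 1.0
plasma_restricted: false
processes:
  - {protein: P-gp, kind: ActiveEffluxMM, K_M: 100.0, k_cat: 2.0, product: sink}
inhibitions: []
metadata:
  fixture: synthetic surrogate
  fraction_metabolized_CYP3A4: 0.0
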