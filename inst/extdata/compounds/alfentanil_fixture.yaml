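# SYNTHETIC victim-drug fixture: simplified whole-body surrogate for
# alfentanil (intermediate-extraction CYP3A4 substrate, short half-life).
# Not a published victim PBPK model.
name: alfentanil
MW: 416.52
pKa:
  - {value: 6.5, type: base}
solubility:
  - {pH: 6.5, mg_per_L: 200.0}
logP: 2.2
fu: 0.1
partition_method: Berezhkovskiy
permeability_method: PKSimStandard
intestinal_permeability:
  fasted: 3.0e-4
  fed: 3.0e-4
GFR_fraction: 0.1
EHC_continuous_fraction: 1.0
plasma_restricted: false
processes:
  - {protein: CYP3A4, kind: MichaelisMenten, K_M: 10.0, k_cat: 8.0, product: sink}
inhibitions: []
metadata:
  fixture: synthetic surrogate
  fraction_metabolized_CYP3A4: 0.9
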