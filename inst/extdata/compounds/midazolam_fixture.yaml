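# SYNTHETIC victim-drug fixture: a simplified whole-body surrogate for
# midazolam with a single hepatic + gut-wall CYP3A4 Michaelis-Menten
# elimination.  Kinetic constants are chosen so that oral half-life,
# clearance and CYP3A4 fraction metabolized fall in literature ranges; the
# fixture is NOT a published victim PBPK model and carries no
# study-specific claims.
name: midazolam
MW: 325.77
pKa:
  - {value: 6.0, type: base}
solubility:
  - {pH: 6.5, mg_per_L: 50.0}
logP: 3.5
fu: 0.02
partition_method: Berezhkovskiy
permeability_method: PKSimStandard
intestinal_permeability:
  fasted: 3.0e-4
  fed: 3.0e-4
GFR_fraction: 0.05
EHC_continuous_fraction: 1.0
plasma_restricted: false
processes:
  - {protein: CYP3A4, kind: MichaelisMenten, K_M: 2.7, k_cat: 20.0, product: sink}
inhibitions: []
metadata:
  fixture: synthetic surrogate
  fraction_metabolized_CYP3A4: 0.94
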