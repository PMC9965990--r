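# N-deacetylketoconazole (M1), formed from ketoconazole by AADAC and
# metabolized to M2 by FMO3.  fu assumed equal to the parent's.
name: m1
MW: 489.40
pKa:
  - {value: 0.20, type: base}
  - {value: 6.42, type: base}
  - {value: 8.90, type: base}
solubility:
  - {pH: 6.5, mg_per_L: 1.24e+03}
logP: 3.75
fu: 0.01
blood_plasma_ratio: 0.62
partition_method: RodgersRowland
permeability_method: SchmittChargeDependent
GFR_fraction: 1.0
EHC_continuous_fraction: 1.0
plasma_restricted: false
processes:
  - {protein: FMO3, kind: MichaelisMenten, K_M: 1.77, k_cat: 378.65, product: m2}
inhibitions:
  - {target_protein: CYP3A4, K_i: 0.022}
  - {target_protein: P-gp,   K_i: 0.119}
metadata:
  logP_literature: 4.58
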