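# N-deacetyl-N-hydroxyketoconazole (M2).  Confined to the intracellular
# space (never observed in plasma): plasma_restricted disables all
# cell/plasma exchange.  Eliminated by an FMO3-normalized first-order
# clearance; inhibition constants surrogated from M1.
name: m2
MW: 505.40
pKa:
  - {value: 3.42, type: base}
  - {value: 6.42, type: base}
solubility:
  - {pH: 6.5, mg_per_L: 4.40e+03}
logP: 4.20
fu: 0.01
blood_plasma_ratio: 0.62
partition_method: Berezhkovskiy
permeability_method: SchmittChargeDependent
GFR_fraction: 1.0
EHC_continuous_fraction: 1.0
plasma_restricted: true
processes:
  - {protein: FMO3, kind: FirstOrderEnzymeNormalized, CL_spec: 0.09, product: sink}
inhibitions:
  - {target_protein: CYP3A4, K_i: 0.022}
  - {target_protein: P-gp,   K_i: 0.119}
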