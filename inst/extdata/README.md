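# Packaged reference data

All files are plain CSV (UTF-8, '.' decimal separator). Units: voltages
mV, times s, concentrations µM.

- `table1_drugs.csv` — drug metadata: 44 drugs with three-letter codes,
  therapeutic class, the concentration tested in the train protocol and
  the human plasma concentration (µM; empty where unavailable).
- `table2_train.csv` — per-drug train-protocol properties (Inh, IC50,
  Rev, UD, τon, τoff with SEMs): 35 analyzed drugs plus 9 dropouts
  (`dropout = 1`; too weak for further characterization). τon of CBZ and
  LID is the 3 s resolution floor, τoff of FLR and LIF the 500 s cap;
  their SEM fields are empty.
- `table3_availability.csv` — per-drug availability-protocol properties
  (Inh at −150 mV, ΔV1/2, Kr, both Ki estimates, SD; literature Kr/Ki
  for reference). Amitriptyline appears at three and riluzole at two
  concentrations. Affinities are geometric means across cells.
- `descriptors_synthetic.csv` — SYNTHETIC chemical-descriptor table:
  plausible stand-in values (approximate literature-magnitude logP, pKa,
  MW, PSA, aromatic atom count, minimal projection area; logD7.3 derived
  from logP and pKa for bases). Not measured reference data; no analysis
  result asserted anywhere depends on these values. `acid = TRUE` marks
  drugs whose dominant ionization is acidic, outside the base-form
  neutral-fraction formula.
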