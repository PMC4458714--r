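# Packaged fixtures

- `mle_interactors_nucleic_acid.tsv` — curated annotation table of the 51
  MS-identified interactors of the Drosophila MLE helicase with a clear
  function in nucleic acid metabolism, transcribed from the source AP-MS
  study's published interactor table.  Columns: protein description,
  biological process, effect of MSL2 knockdown on the interaction, effect of
  RNase treatment on the interaction (`Decrease`, `Increase`, or blank for
  no significant effect).  Loaded by `interactor_annotations()`.

All other inputs used in tests and examples are generated at run time by the
`sim_*` generators (see `?simulation_spec`); nothing here is downloaded.
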