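# Example column dialect: maps canonical field names to the headers of a
# legacy file. `sep` overrides the separator passed to read_experiment_table.
sep: "\t"
columns:
  study_id: Site
  plot_id: Plot
  year: Yr
  sown_richness: SownDiv
  treatment: Trt
  species_id: Species
  sown_proportion: SownProp
  biomass: AGB_g_m2
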