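# data.table is used via :: but with NSE inside [.data.table
.datatable.aware <- TRUE

utils::globalVariables(c(
  "multiallelic", "n_supported", "rna_alt_count", "rna_alt_freq",
  "alt_base", "ref_base", "all_ones", "n_samples", "distance", "is_min",
  "significant", "rho", "synonymous", "."))
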