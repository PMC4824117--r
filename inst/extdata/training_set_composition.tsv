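# Published composition of the curated variant training set and of the SSC
# de novo missense cohort; counts only, ratios are recomputed downstream.
quantity	count
variants_human	5901
variants_other_eukaryote	1635
variants_prokaryote	1725
variants_archaeal	122
variants_viral	94
variants_deleterious	5740
variants_neutral	3737
ssc_proband	1335
ssc_sibling	891
ssc_mapped_to_structure	1644
ssc_sequence_only	582
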