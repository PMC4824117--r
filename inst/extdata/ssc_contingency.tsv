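# Published 2x2 prediction counts on the Simons Simplex Collection de novo
# missense set (1335 proband, 891 unaffected-sibling mutations), per method,
# at the 0.5 score cutoff.  Columns: proband/sibling mutations predicted
# deleterious (D) or neutral (N).  Used as input to contingency_enrichment().
method	proband_D	proband_N	sibling_D	sibling_N
BLOSUM62	907	428	566	325
combined	554	781	348	543
SIFT	779	556	499	392
PolyPhen2	769	566	494	397
CADD	747	588	499	392
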