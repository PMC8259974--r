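# UniProt sequences commonly used as crystallization chaperones / fusion
# partners; skipped when resolving clashing accessions on chimeric chains.
GFP_AEQVI
GCN4_YEAST
C562_ECOLX
ENLYS_BPT4
MALE_ECOLI
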