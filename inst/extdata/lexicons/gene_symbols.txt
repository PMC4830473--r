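# Seed gene-symbol list. A full HUGO-scale list is deliberately not bundled;
# supply your own with read_lexicon() / lexicon_set().
TP53
EGFR
KRAS
BRAF
ATM
MEN1
BRCA1
BRCA2
PIK3CA
PTEN
ALK
KIT
ERBB2
JAK2
FLT3
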