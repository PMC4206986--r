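# Literature-curated regulatory direction of transcription factors with
# respect to the mTOR pathway: "regulating" (acts on the pathway),
# "regulated" (a pathway target), or "both". Direction is annotation only
# and is never inferred from motif data. User-editable.
SP1: both
KLF4: regulating
TBP: regulated
ELK1: regulated
ESR1: regulated
E2F1: regulating
FOXF2: regulating
EGR1: regulating
ARNT: regulating
TFAP2A: regulating
MEF2A: regulating
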