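# Pathway-module membership of mTOR-pathway genes (core + modules 1-10),
# as far as the study narrative states them; genes not listed are treated
# as "unassigned". User-editable annotation, not computed by the pipeline.
INS: module_1
MAPK3: module_1
RPS6KA2: module_1
RPS6KA3: module_1
IRS1: module_2
PIK3R1: module_2
PIK3R2: module_2
PIK3CA: module_2
AKT1: module_2
PTEN: module_2
TNF: module_3
TSC2: module_4
DDIT4: module_4
RRAGC: module_5
RRAGD: module_5
VEGFA: module_7
EIF4E1B: module_7
RPS6KB1: module_7
ULK1: module_8
STRADA: module_10
STK11: module_10
CAB39: module_10
MTOR: core
RHEB: core
RICTOR: core
RPTOR: core
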