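# Synthetic demonstration table of tumor-suppressor / oncogene roles for
# kinases, in the two-column layout annotate_ts() expects (gene, role).
# This is NOT the literature-mined resource itself; supply your own export
# of such a resource for real analyses.
gene	role
ATM	tumor_suppressor
CHEK2	tumor_suppressor
STK11	tumor_suppressor
MAP2K4	tumor_suppressor
GSK3B	tumor_suppressor
ABL1	oncogene
SRC	oncogene
KIT	oncogene
FLT3	oncogene
EGFR	oncogene
ERBB2	oncogene
AKT1	oncogene
PIM1	oncogene
AURKA	oncogene
CDK4	oncogene
MTOR	oncogene
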