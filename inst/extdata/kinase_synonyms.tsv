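# Curated kinase-name synonym map: raw names as they appear in public
# kinase-substrate databases -> canonical HGNC gene symbols. Best-effort
# curation; user-replaceable via read_kinase_synonyms(path).
raw	canonical
CK2A1	CSNK2A1
CK2a1	CSNK2A1
CK2alpha	CSNK2A1
CK1d	CSNK1D
CK1delta	CSNK1D
CK1e	CSNK1E
CK1epsilon	CSNK1E
CK1a	CSNK1A1
PKACA	PRKACA
PKA-alpha	PRKACA
PKCa	PRKCA
PKCalpha	PRKCA
PKCb	PRKCB
PKCbeta	PRKCB
PKCd	PRKCD
PKCdelta	PRKCD
PKCe	PRKCE
PKCepsilon	PRKCE
PKCi	PRKCI
PKCiota	PRKCI
PKCg	PRKCG
PKCgamma	PRKCG
ERK1	MAPK3
ERK2	MAPK1
JNK1	MAPK8
JNK2	MAPK9
JNK3	MAPK10
p38	MAPK14
p38a	MAPK14
p38alpha	MAPK14
p38b	MAPK11
p38beta	MAPK11
p38g	MAPK12
p38gamma	MAPK12
p38d	MAPK13
p38delta	MAPK13
MEK1	MAP2K1
MEK2	MAP2K2
MKK4	MAP2K4
MKK7	MAP2K7
ABL	ABL1
Abl	ABL1
ARG	ABL2
PDK1	PDPK1
PDHK1	PDK1
AurA	AURKA
Aurora-A	AURKA
AurB	AURKB
Aurora-B	AURKB
CDC2	CDK1
cdc2	CDK1
mTOR	MTOR
FRAP	MTOR
p70S6K	RPS6KB1
RSK1	RPS6KA1
RSK2	RPS6KA3
RSK3	RPS6KA2
MSK1	RPS6KA5
MK2	MAPKAPK2
CHK1	CHEK1
CHK2	CHEK2
PLK	PLK1
SGK	SGK1
AKT	AKT1
PKB	AKT1
PKBalpha	AKT1
PKBbeta	AKT2
GSK3	GSK3B
GSK3beta	GSK3B
GSK3alpha	GSK3A
TTK/MPS1	TTK
MPS1	TTK
ICK	CILK1
AMPKa1	PRKAA1
AMPKa2	PRKAA2
CaMK2a	CAMK2A
CaMK2g	CAMK2G
CaMK4	CAMK4
DNAPK	PRKDC
DNA-PK	PRKDC
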