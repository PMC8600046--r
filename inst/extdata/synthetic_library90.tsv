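protein	annotation
ABCD1	peroxisome_db
ABCD2	peroxisome_db
ABCD3	peroxisome_db
ABCD4	peroxisome_db
ACAA1	peroxisome_db
ACAD11	peroxisome_db
ACBD4	peroxisome_db
ACBD5	peroxisome_db
ACOT4	peroxisome_db
ACOT8	peroxisome_db
ACOX1	peroxisome_db
ACOX2	peroxisome_db
ACOX3	peroxisome_db
AGPS	peroxisome_db
AGXT	peroxisome_db
ALDH3A2	peroxisome_db
AMACR	peroxisome_db
ATAD1	peroxisome_db
BAAT	peroxisome_db
CAT	peroxisome_db
CRAT	peroxisome_db
CROT	peroxisome_db
DAO	peroxisome_db
DDO	peroxisome_db
DECR2	peroxisome_db
DHRS4	peroxisome_db
DNM1L	peroxisome_db
ECH1	peroxisome_db
ECI2	peroxisome_db
EHHADH	peroxisome_db
EPHX2	peroxisome_db
FAR1	peroxisome_db
FAR2	peroxisome_db
FIS1	peroxisome_db
GNPAT	peroxisome_db
GRHPR	peroxisome_db
GSTK1	peroxisome_db
HACL1	peroxisome_db
HAO1	peroxisome_db
HAO2	peroxisome_db
HMGCL	peroxisome_db
HSD17B4	peroxisome_db
IDE	peroxisome_db
IDH1	peroxisome_db
IDH2	peroxisome_db
ISOC1	peroxisome_db
LONP2	peroxisome_db
MAVS	peroxisome_db
MFF	candidate
MGST1	peroxisome_db
MLYCD	peroxisome_db
MPV17L2	candidate
MVK	peroxisome_db
NUDT12	peroxisome_db
NUDT19	peroxisome_db
NUDT7	peroxisome_db
PAOX	peroxisome_db
PECR	peroxisome_db
PEX1	peroxisome_db
PEX10	peroxisome_db
PEX11A	peroxisome_db
PEX11B	peroxisome_db
PEX11G	peroxisome_db
PEX12	peroxisome_db
PEX13	peroxisome_db
PEX14	peroxisome_db
PEX16	peroxisome_db
PEX19	peroxisome_db
PEX2	peroxisome_db
PEX3	peroxisome_db
PEX5	peroxisome_db
PEX6	peroxisome_db
PEX7	peroxisome_db
PHYH	peroxisome_db
PIPOX	peroxisome_db
PRDX1	peroxisome_db
PRDX5	peroxisome_db
PXMP2	peroxisome_db
PXMP4	peroxisome_db
PXT1	candidate
RIDA	peroxisome_db
SCP2	peroxisome_db
SLC25A17	peroxisome_db
SLC27A2	peroxisome_db
SOD1	peroxisome_db
TMEM135	peroxisome_db
TRIM37	peroxisome_db
TYSND1	peroxisome_db
XDH	peroxisome_db
ZADH2	peroxisome_db
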