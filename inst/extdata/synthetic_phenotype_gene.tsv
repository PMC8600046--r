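gene	phenotype	mim_id	basis
PEX1	ZS	MIM:100137	known molecular basis
PEX2	ZS	MIM:100137	known molecular basis
PEX3	ZS	MIM:100137	known molecular basis
PEX5	ZS	MIM:100137	known molecular basis
PEX6	ZS	MIM:100137	known molecular basis
PEX10	ZS	MIM:100137	known molecular basis
PEX11B	ZS	MIM:100137	known molecular basis
PEX12	ZS	MIM:100137	known molecular basis
PEX13	ZS	MIM:100137	known molecular basis
PEX14	ZS	MIM:100137	known molecular basis
PEX16	ZS	MIM:100137	known molecular basis
PEX19	ZS	MIM:100137	known molecular basis
PEX26	ZS	MIM:100137	known molecular basis
PEX10	NALD	MIM:100274	known molecular basis
PEX13	NALD	MIM:100274	known molecular basis
PEX16	NALD	MIM:100274	known molecular basis
PEX26	NALD	MIM:100274	known molecular basis
PEX1	IRD	MIM:100411	known molecular basis
PEX2	IRD	MIM:100411	known molecular basis
PEX6	IRD	MIM:100411	known molecular basis
PEX10	IRD	MIM:100411	known molecular basis
PEX12	IRD	MIM:100411	known molecular basis
PEX26	IRD	MIM:100411	known molecular basis
PEX1	Heimler syndrome	MIM:100548	known molecular basis
PEX6	Heimler syndrome	MIM:100548	known molecular basis
PEX7	RCDP1	MIM:100685	known molecular basis
PEX5	RCDP5	MIM:100822	known molecular basis
PHYH	Refsum disease	MIM:100959	known molecular basis
PEX7	Refsum disease	MIM:100959	known molecular basis
AGPS	RCDP3	MIM:101096	known molecular basis
ABCD1	X-linked adrenoleukodystrophy	MIM:101233	known molecular basis
ALDH3A2	Sjogren-Larsson syndrome	MIM:101370	known molecular basis
PEX11B	PBD14B	MIM:101507	known molecular basis
DNM1L	EMPF1	MIM:101644	known molecular basis
DNM1L	Optic atrophy 5	MIM:101781	known molecular basis
MFF	EMPF2	MIM:101918	known molecular basis
CAT	Acatalasemia	MIM:102055	known molecular basis
AGXT	Primary hyperoxaluria type 1	MIM:102192	known molecular basis
ACOX1	ACOX1 deficiency	MIM:102329	known molecular basis
ACOX1	Mitchell syndrome	MIM:102466	known molecular basis
SCP2	Leukoencephalopathy with dystonia and motor neuropathy	MIM:102603	known molecular basis
HSD17B4	D-bifunctional protein deficiency	MIM:102740	known molecular basis
EHHADH	Fanconi renotubular syndrome 3	MIM:102877	known molecular basis
ABCD4	Methylmalonic aciduria and homocystinuria, cblJ type	MIM:103014	known molecular basis
AMACR	AMACR deficiency	MIM:103151	known molecular basis
AMACR	Congenital bile acid synthesis defect 4	MIM:103288	known molecular basis
BAAT	Familial hypercholanemia	MIM:103425	known molecular basis
MLYCD	Malonyl-CoA decarboxylase deficiency	MIM:103562	known molecular basis
XDH	Xanthinuria type 1	MIM:103699	known molecular basis
TRIM37	Mulibrey nanism	MIM:103836	known molecular basis
SOD1	Amyotrophic lateral sclerosis 1	MIM:103973	known molecular basis
MVK	Mevalonic aciduria	MIM:104110	known molecular basis
MVK	Hyper-IgD syndrome	MIM:104247	known molecular basis
GRHPR	Primary hyperoxaluria type 2	MIM:104384	known molecular basis
ATAD1	Hyperekplexia 4	MIM:104521	known molecular basis
GNPAT	RCDP2	MIM:104658	known molecular basis
FAR2	RCDP2	MIM:104658	known molecular basis
ACOX2	Congenital bile acid synthesis defect 6	MIM:104795	known molecular basis
DAO	Schizophrenia, susceptibility	MIM:104932	known molecular basis
DDO	Schizophrenia, susceptibility	MIM:104932	known molecular basis
HAO1	Glycolate oxidase deficiency	MIM:105069	known molecular basis
CRAT	Neurodegeneration with brain iron accumulation, atypical	MIM:105206	known molecular basis
CROT	Neurodegeneration with brain iron accumulation, atypical	MIM:105206	known molecular basis
TYSND1	Prostate cancer, susceptibility	MIM:105343	known molecular basis
PRDX5	Multiple sclerosis, susceptibility	MIM:105480	known molecular basis
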