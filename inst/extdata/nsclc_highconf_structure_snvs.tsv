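gene	mrna	utr	snv	p_d	conserved_d	p_r	conserved_r	dbsnp_id
GSR	NM_001195102	3	A2638G	0.0030	89^rnaz	0.0213	100^rnaz	rs1138092
MEF2A	NM_005587	3	A2046U	0.0032	100^rnaz	0.0238	100^rnaz	
PPM1A	NM_177952	3	G2231A	0.0059	100^cmfinder	0.0118	100^cmfinder	
MAPK14	NM_139012	3	A2304C	0.0076	100^cmfinder;96^rnaz	0.0224	91^cmfinder;91^rnaz	
PHC2	NM_198040	3	A3730C	0.0105	-	0.0137	75^cmfinder	
BECN1	NM_003766	3	U1970C	0.0120	100^cmfinder	0.0487	100^cmfinder	
NFKBIE	NM_004556	3	G1659C	0.0144	84^rnaz	0.0473	100^rnaz	
MAPK1	NM_002745	3	U2360G	0.0148	100^cmfinder	0.0262	100^cmfinder	rs13058
DHCR24	NM_014762	3	A4192C	0.0159	100^cmfinder	0.0494	100^cmfinder	
ADAMTS1	NM_006988	3	U4320G	0.0166	94^cmfinder	0.0215	83^cmfinder	
SRF	NM_003131	3	C3504U	0.0173	100^cmfinder	0.0074	100^cmfinder	rs3734681
CASP2	NM_032982	3	U2139C	0.0189	56^cmfinder	0.0230	62^cmfinder	
LFNG	NM_001040167	3	C1838G	0.0215	64^cmfinder	0.0333	-	rs4721752
SH3PXD2A	NM_014631	3	C8560U	0.0223	100^rnaz	0.0073	-	
KITLG	NM_000899	3	U1057G	0.0226	50^rnaz;84^cmfinder	0.0080	90^cmfinder	
PRKAB1	NM_006253	3	U1875C	0.0237	100^rnaz	0.0462	100^rnaz	
TFG	NM_001195479	5	G309C	0.0256	-	0.0398	56^cmfinder	
FTH1	NM_002032	3	U819G	0.0262	93^cmfinder	0.0259	100^cmfinder	
BCL2L2	NM_001199839	3	C2469A	0.0275	78^cmfinder	0.0294	100^cmfinder	rs3210043
CDKN1C	NM_000076	3	G1334C	0.0290	87^cmfinder	0.0253	87^cmfinder	
TIA1	NM_022173	3	U4082A	0.0316	100^cmfinder	0.0363	100^cmfinder	
NFKBIE	NM_004556	3	U1644G	0.0333	98^cmfinder	0.0347	100^cmfinder	
DAPK3	NM_001348	3	G1662U	0.0334	54^cmfinder	0.0216	94^cmfinder	rs3745982
NCOA1	NM_003743	3	C4893G	0.0342	100^cmfinder	0.0176	100^cmfinder	rs17737058
PCBP4	NM_001174100	3	C1790G	0.0413	59^cmfinder	0.0187	-	
SH3PXD2A	NM_014631	3	U8562A	0.0451	100^rnaz	0.0096	100^rnaz	
ID2	NM_002166	5	C143G	0.0464	87^cmfinder	0.0474	83^cmfinder	
GPX3	NM_002084	3	U1552G	0.0474	73^cmfinder	0.0427	100^cmfinder	
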