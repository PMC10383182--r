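gene	peptide	site	p_value	direction
ACSA	SWSPPPEVSR	S3:Phospho	0.00240942	up
AMNLS	RLSLVPK	S3:Phospho	0.01164248	up
BAIP2	AFPAQTASGFK	T6:Phospho	0.003610772	up
BAIP2	LSDSYSNTLPVR	T8:Phospho	0.00927998	up
CHSP1	GNVVPSPLPTR	S6:Phospho	0.011014319	up
ES8L1	SLNSTPPPPPAPAPAPPPALAR	T5:Phospho	0.031333883	up
FIBA	PGSTGTWNPGSSER	S11:Phospho	0.003771194	up
GSK3B	GEPNVSYICSR	Y7:Phospho	0.028989048	up
GPC5B	TAGFPNGSLGK	S8:Phospho	0.022155551	up
GPC5C	ATANSQVMGSANSTLR	S13:Phospho	0.010074399	up
K1C13	MIGFPSSAGSVSPR	S12:Phospho	0.003025495	up
KIF12	SPGQVLPPH	S1:Phospho	1.37e-10	up
MAP1A	TLPQEPGK	T1:Phospho	0.00176674	up
MILK1	SPVPSPGSSSPQLQVK	S10:Phospho	0.022496032	up
MY15B	AVPSPPPPPIVK	S4:Phospho	0.001997071	up
NAT8L	MSVDSRFR	S5:Phospho	0.029409743	up
NPT2A	LGSPAVSPLPVR	S7:Phospho	0.002418861	up
PDZ1I	YSSMAASFR	S7:Phospho	0.004247949	up
SHAN2	RAPSPVVSPTEMNK	S4:Phospho	0.035395595	up
VINEX	AIETRLPSPK	T4:Phospho	0.003764395	up
VP37D	SAQPAPTSAADPPK	S1:Phospho	0.023114006	up
YG015	IELSYNK	Y5:Phospho	0.002020309	up
ZNF25	SHFIIHQR	S1:Phospho	0.003312002	up
AQP2	RQSVELHSPQSLPR	S3:Phospho	0.001562435	down
AQP2	RRQSVELHSPQSLPR	S4:Phospho	0.001865546	down
CAN7L	INSAHGSDKSK	S3:Phospho	0.005547201	down
CF170	KWMHAHYSR	S8:Phospho	8.55e-6	down
CHM4C	LPNVPSSSLPAQPNR	S8:Phospho	0.03478666	down
CI169	NPYAHISIPR	S7:Phospho	0.014805139	down
CK052	TLKPQPQQLQQNLPK	T1:Phospho	0.015894205	down
CP250	QSESLSELITLR	S2:Phospho	0.007130084	down
CSPP1	QPSPIVPALQNK	S3:Phospho	0.000997041	down
EPS8	APAPAPPGTVTQVDVR	T9:Phospho	0.001709885	down
EPS8	KGPGEGVLTLR	T9:Phospho	0.003312002	down
ES8L2	HSPTSEPTPPGDALPPVSSPHTHR	S19:Phospho	0.041726109	down
EZRI	QLLTLSSELSQAR	T4:Phospho	3.66e-6	down
GPC5C	VPSEGAYDIILPR	S3:Phospho	0.00052554	down
ICK	STPGLIPRPPAAQPVHGR	T2:Phospho	0.021340709	down
IF4E2	TASDQATTARIR	S3:Phospho	0.019186167	down
LDHA	TPKIVSGK	T1:Phospho	0.020570378	down
LMNA	SGAQASSTPLSPTRITR	S11:Phospho	0.00927998	down
MUC1	DTYHPMSEYPTYHTHGR	S7:Phospho	0.035395595	down
RAB10	FHTITTSYYR	T3:Phospho	0.006517696	down
RAI3	AHAWPSPYKDYEVK	S6:Phospho	0.01798913	down
SARG	ANSALTPPKPESGLTLQESNTPGLR	T6:Phospho	0.019581944	down
SHS6L	TPNLDWR	T1:Phospho	0.000684591	down
TRPV5	ASLALPTSSLSR	S11:Phospho	0.00176674	down
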