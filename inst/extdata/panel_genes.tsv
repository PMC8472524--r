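gene	evidence_level	drugs	tumor_types
AKT1	B	AZD-5363	breast;ovary;endometrial
ALK	A	Ceritinib;Crizotinib;Alectinib;Brigatinib;Lorlatinib	NSCLC
ARID1A	C	Trastuzumab;ENMD-2076;Bevacizumab;Everolimus	breast;ovary_clear_cell;renal
BRAF	A	Encorafenib + Cetuximab;Vemurafenib;Dabrafenib;Trametinib + Dabrafenib;Cobimetinib + Vemurafenib;Trametinib;Encorafenib + Binimetinib;Encorafenib + Panitumumab	colorectal;melanoma;NSCLC;thyroid
BRCA1	A	Olaparib;Niraparib;Rucaparib;Talazoparib	ovary;peritoneal;breast;prostate;pancreatic
BRCA2	A	Olaparib;Rucaparib;Talazoparib	ovary;peritoneal;breast;prostate
CDK4	B	Palbociclib;Abemaciclib	liposarcoma
EGFR	A	Erlotinib;Afatinib;Osimertinib;Gefitinib;Dacomitinib	NSCLC
ERBB2	A	Trastuzumab;Fam-Trastuzumab deruxtecan-nxki;Trastuzumab + Pembrolizumab;Afatinib	breast;gastric;gastroesophageal;NSCLC
ESR1	B	Anastrozole;Fulvestrant;Palbociclib	breast
IDH2	A	Enasidenib	AML
KIT	A	Sunitinib;Imatinib;Regorafenib;Sorafenib;Ripretinib	GIST;melanoma
KRAS	A	Cetuximab;Panitumumab;Erlotinib;Lapatinib;Regorafenib;Selumetinib;Gefitinib;Afatinib;Icotinib;Irinotecan	colorectal;NSCLC
MET	A	Crizotinib;Capmatinib;Tepotinib	NSCLC
MTOR	B	Everolimus;Temsirolimus	renal;bladder
NRAS	A	Cetuximab;Panitumumab	colorectal
PDGFRA	A	Imatinib;Sunitinib;Regorafenib	GIST
PIK3CA	A	Buparlisib;Serabelisib;Alpelisib;Copanlisib	breast
PTCH1	A	Vismodegib	BCC;SCC;medulloblastoma
PTEN	B	Everolimus;Pembrolizumab;Cetuximab;Sorafenib	renal;glioma;HNSC;colorectal;HCC
ROS1	C	Crizotinib;Alectinib;Ceritinib	NSCLC
SMO	B	Vismodegib	BCC
TP53	A	Prognosis	various
TSC1	A	Everolimus	GCA;renal;angiomyolipoma
TSC2	A	MTOR inhibitors	GCA;renal;angiomyolipoma
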