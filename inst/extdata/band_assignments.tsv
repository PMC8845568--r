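wavenumber	density_psyringae	density_bsubtilis	assignment
623	-0.0103	0.0000	623 adenine
645	-0.0047	0.0003	645 cytosine, adenine
669	0.0139	0.0066	668 guanine
726	0.0031	0.0180	723/724 adenine
748	-0.0094	-0.0154	740 thymine
784	0.0634	0.03444	785 cytosine/uracil
855	-0.0399	0.0049	848 ribose/O-P-O stretch
902	-0.0471	-0.0042	Various metabolites
961	-0.0598	0.0006	960 Valine/leucine
1005	-0.1428	0.0020	1,004 Phenylalanine
1034	-0.0626	0.0014	1,035 proteins/1034 phosphoenolpyruvate
1096	-0.0084	0.0078	1,101 PO2-
1175	-0.0207	-0.0035	1,174 L-histidine
1241	-0.0018	0.0189	1,230-1,310 amide III interval, 1240 uracil
1336	0.0442	0.0072	1,337 adenine
1452	-0.0466	-0.0090	1,440 lipids
1482	0.0922	0.0346	1,482 guanine/adenine
1577	0.1333	-0.0207	1,573 adenine, guanine
1671	-0.1031	0.0397	1,640-1,680 amide 1, 1,671 thymine
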