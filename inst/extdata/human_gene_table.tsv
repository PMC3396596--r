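gene_symbol	ncbi_gene_id	full_name	ensembl_gene_id	ensembl_protein_id	protein_length	location
HEY1	23462	HEY1 hairy/enhancer-of-split related with YRPW motif 1	ENSG00000164683	ENSP00000338272	308	Chr:8:80676248:80680092:-1
HEY2	23493	HEY2 hairy/enhancer-of-split related with YRPW motif 2	ENSG00000135547	ENSP00000357348	337	Chr:6:126070726:126082415:1
HEYL	26508	HEYL hairy/enhancer-of-split related with YRPW motif-like	ENSG00000163909	ENSP00000361943	328	Chr:1:40089825:40105617:-1
BHLHE40	8553	BHLHE40 basic helix-loop-helix family, member e40	ENSG00000134107	ENSP00000256495	412	Chr:3:5020801:5027008:1
BHLHE41	79365	BHLHE41 basic helix-loop-helix family, member e41	ENSG00000123095	ENSP00000242728	482	Chr:12:26272959:26278060:-1
HELT	391723	HELT helt bHLH transcription factor	ENSG00000187821	ENSP00000426033	242	Chr:4:185939995:185941950:1
HES1	3280	HES1 hairy and enhancer of split 1	ENSG00000114315	ENSP00000232424	280	Chr:3:193853934:193856521:1
HES4	57801	HES4 hairy and enhancer of split 4	ENSG00000188290	ENSP00000304595	221	Chr:1:934344:935491:-1
HES6	55502	HES6 hairy and enhancer of split 6	ENSG00000144485	ENSP00000272937	224	Chr:2:239146908:239148765:-1
HES2	54626	HES2 hairy and enhancer of split 2	ENSG00000069812	ENSP00000367065	173	Chr:1:6475292:6479979:-1
HES3	390992	HES3 hairy and enhancer of split 3	ENSG00000173673	ENSP00000367130	186	Chr:1:6304252:6305638:1
HES5	388585	HES5 hairy and enhancer of split 5	ENSG00000197921	ENSP00000367714	166	Chr:1:2460184:2461684:-1
HES7	84667	HES7 hairy and enhancer of split 7	ENSG00000179111	ENSP00000314774	225	Chr:17:8023908:8027410:-1
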