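strain	orf	cwss	pilin_motif	ebox
B. bifidum PRL2010	283	LPKTGA	GDSTAEVDMK	YTVTETAVADGY
B. bifidum PRL2010	1707	LPLTGG	VYSSGSIDMK	YTIEEIAAPNGY
B. bifidum PRL2010	1821	LPGTGG	HSTTVGVDIK	YTLTETEAPAGY
B. dentium Bd1	144	LPLTGA	NHGDNTVNMK	YTVSETKVATGQ
B. dentium Bd1	200	LPLTGG	QTLSYNVTAK	YTVKETKAPAGY
B. dentium Bd1	277	LPETGG	VAGNVTITPK	YVLTETKTPAGY
B. dentium Bd1	535	LPLTGA	GQTLGVVNVK	YDVVETDAPAGY
B. dentium Bd1	1875	LPITGA	HPAQTIDVKK	YTVTETVVPAGF
B. dentium Bd1	2190	LPSTGG	FEKINSVKVK	YVLSETKTPEGY
B. dentium Bd1	1999	LPLTGA	PLTLGTVVAK	YTVKETATREDL
B. longum subsp. longum NCC2705	675	LPDTGG	KSEYPTVDKT	YYLKETFAPKGY
B. longum subsp. longum DJ010A	1468	LPGTGG	KGSLPTVDKK	YTLTETKAPAGY
B. adolescentis ATCC 15703	1463	LPLTGA	INAVGMFVAK	YTLKETGFASGY
B. animalis subsp. lactis DSM10140	1484	LPLTGA	KPSGTITLGK	YKVTETDVLSRY
A. naeslundii T14V	FimP	LPLTGA	WNYNVHVYPK	YCLVETKAPEGY
A. naeslundii T14V	FimA	LPLTGA	WIYDVHVYPK	YVLVETKAPAGY
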