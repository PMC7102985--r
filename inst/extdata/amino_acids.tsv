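aa	class	group	route	delta_na	n_sa
Ser	II	GA	F6P,G3P,Ser	0	2
Gly	II	GA	F6P,G3P,Ser,Gly	0	0
Ala	II	GA	F6P,G3P,PEP,Pyrv,Ala	0	1
Cys	I	GA	F6P,G3P,Ser,Cys	0	2
Thr	II	GA	F6P,G3P,Ser,Gly,Thr	0	3
Val	I	GA	F6P,G3P,PEP,Pyrv,Val	0	3
Leu	I	GA	F6P,G3P,PEP,Pyrv,Leu	0	4
Ile	I	GA	F6P,G3P,Ser,Gly,Thr,Ile	0	4
Asp	II	GB	F6P,G3P,PEP,Pyrv,AcCoA,TCA,OXA,Asp	0	4
Asn	II	GB	F6P,G3P,PEP,Pyrv,AcCoA,TCA,OXA,Asp,Asn	0	4
Met	I	GB	F6P,G3P,PEP,Pyrv,AcCoA,TCA,OXA,Asp,Met	0	4
Lys	II	GB	F6P,G3P,PEP,Pyrv,AcCoA,TCA,OXA,Asp,Lys	0	5
Glu	I	GB	F6P,G3P,PEP,Pyrv,AcCoA,TCA,2OG,Glu	0	5
Gln	I	GB	F6P,G3P,PEP,Pyrv,AcCoA,TCA,2OG,Glu,Gln	0	5
Pro	II	GB	F6P,G3P,PEP,Pyrv,AcCoA,TCA,2OG,Glu,Pro	0	3
Arg	I	GB	F6P,G3P,PEP,Pyrv,AcCoA,TCA,2OG,Glu,Arg	0	7
Phe	II	GC	F6P,PPPcore,E4P,Cr,Phe	10	7
Tyr	I	GC	F6P,PPPcore,E4P,Cr,Tyr	10	8
Trp	I	GC	F6P,PPPcore,E4P,Cr,Trp	10	10
His	II	GC	F6P,PPPcore,His	20	6
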