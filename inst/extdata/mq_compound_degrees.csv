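rank,compound,score
1,Methyl 2-methylbutyrate,169
2,m-Cymene,169
3,trans-Verbenol,154
4,gamma-Terpinene,146
5,Fenchol,143
6,1R-alpha-Pinene,141
7,1S-alpha-Pinene,141
8,Terpinen-4-ol,139
9,Isoborneol,134
10,"1,8-Cineole",133
11,(+)-3-Carene,129
12,alpha-Guaiene,127
13,trans-Ocimenol,120
14,(-)-Palustrol,101
15,(-)-Globulol,98
16,Viridiflorol,98
17,Ledol,98
18,Caryophyllene oxide,97
19,(+)-Ledene,96
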