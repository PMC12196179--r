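peak_id,rt,name,chemical_class,ri_exp,ri_lit,area_pct
1,3.540,Methyl 2-methylbutyrate,Fatty acid ester,769,767,0.04
2,7.565,1R-alpha-Pinene,Bicyclic monoterpene hydrocarbon,923,922,15.97
3,8.725,1S-alpha-Pinene,Bicyclic monoterpene hydrocarbon,962,963,5.29
4,10.075,m-Cymene,Aromatic monoterpene hydrocarbon,1006,1005,1.54
5,10.305,"1,8-Cineole",Monocyclic monoterpene oxide,1013,1013,31.57
6,10.370,(+)-3-Carene,Aromatic monoterpene hydrocarbon,1015,1015,11.57
7,11.230,gamma-Terpinene,Monocyclic monoterpene hydrocarbon,1043,1042,0.58
8,12.750,Fenchol,Monocyclic monoterpene alcohol,1091,1097,0.24
9,14.275,Isoborneol,Bicyclic monoterpene alcohol,1141,1147,0.48
10,14.680,Terpinen-4-ol,Monocyclic monoterpene alcohol,1154,1152,0.80
11,14.950,trans-Verbenol,Bicyclic monoterpene alcohol,1163,1155,0.11
12,15.065,trans-Ocimenol,Acyclic monoterpene alcohol,1167,1169,8.26
13,22.955,alpha-Guaiene,Bicyclic sesquiterpene hydrocarbon,1445,1440,0.16
14,23.860,(+)-Ledene,Bicyclic sesquiterpene hydrocarbon,1480,1482,0.24
15,25.590,(-)-Palustrol,Bicyclic sesquiterpene alcohol,1561,1562,0.56
16,25.795,Caryophyllene oxide,Tricyclic sesquiterpene oxide,1572,1578,2.23
17,25.930,(-)-Globulol,Tricyclic sesquiterpene alcohol,1578,1580,0.25
18,26.135,Viridiflorol,Tricyclic sesquiterpene alcohol,1589,1587,13.65
19,26.390,Ledol,Tricyclic sesquiterpene alcohol,1601,1599,4.55
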