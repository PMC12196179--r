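agent,cell_line,kind,value,sd
MQLEO,Vero,CC50,77.76,3.96
MQLEO,MCF-7,IC50,27.74,1.41
MQLEO,HepG-2,IC50,66.04,3.36
MQLEO,A-549,IC50,18.09,0.92
Staurosporine,Vero,CC50,24.20,1.23
Staurosporine,MCF-7,IC50,4.62,0.24
Staurosporine,HepG-2,IC50,9.51,0.48
Staurosporine,A-549,IC50,3.92,0.20
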