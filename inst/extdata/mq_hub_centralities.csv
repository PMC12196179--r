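node,bc,cc,dc
ESR1,8287.888526,0.26860565,99
CASP3,4448.232593,0.2670068,93
PPARG,5617.635482,0.2652027,88
PTGS2,5493.159146,0.26430976,85
HSP90AA1,3015.111312,0.26079734,82
MMP9,3298.324704,0.25950413,82
GSK3B,3013.523609,0.26036484,71
HSP90AB1,1607.859991,0.25570033,69
SIRT1,2215.048411,0.25737705,68
APP,3729.932474,0.25632653,63
KDR,2429.196004,0.25220884,57
ICAM1,1813.331077,0.25445705,56
CYP3A4,2092.784051,0.25160256,55
ACE,2263.673069,0.25322581,54
NR3C1,2162.884329,0.25570033,54
PPARA,2315.896888,0.25160256,52
MAOA,2097.54489,0.25039872,51
MAOB,1518.447362,0.24666143,48
MAPK14,1912.303096,0.24782952,45
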