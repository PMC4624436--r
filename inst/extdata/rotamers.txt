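# Rotamer library: residue, rotamer name, rotameric chi angles (degrees).
# Values follow the common penultimate-style rotamer positions for the 18
# chi-bearing amino-acid types; whitespace-delimited, one rotamer per line.
SER p 64
SER t 178
SER m -65
CYS p 62
CYS t -177
CYS m -65
THR p 62
THR t -175
THR m -65
VAL t 175
VAL m -60
VAL p 63
ILE mt -65 170
ILE mm -57 -60
ILE pt 62 170
LEU mt -65 175
LEU tp 177 65
LEU mp -85 65
PRO endo 30 -35
PRO exo -29 35
ASP m-20 -70 -15
ASP t0 -177 3
ASP p-10 62 -10
ASN m-40 -65 -40
ASN t0 -174 -2
ASN p-10 62 -13
PHE m-85 -65 -85
PHE t80 177 80
PHE p90 62 90
TYR m-85 -65 -85
TYR t80 177 80
TYR p90 62 90
TRP m95 -65 95
TRP t-105 177 -105
TRP p-90 62 -90
HIS m-70 -65 -70
HIS t60 -177 60
HIS p80 62 80
MET mmm -65 -65 -70
MET mtp -67 180 75
MET ttp 180 180 75
MET ptm 62 180 -75
GLU mm-40 -65 -65 -40
GLU mt-10 -67 180 -10
GLU tt0 -177 180 0
GLU pt-20 62 180 -20
GLN mm-40 -65 -65 -40
GLN mt-30 -67 180 -25
GLN tt0 -177 180 0
GLN pt20 62 180 20
LYS mttt -67 180 180 180
LYS tttt 180 180 180 180
LYS pttt 62 180 180 180
LYS mmtt -65 -68 180 180
ARG mtt180 -67 180 180 180
ARG ttt180 180 180 180 180
ARG ptt180 62 180 180 180
ARG mtm180 -67 180 -65 180
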