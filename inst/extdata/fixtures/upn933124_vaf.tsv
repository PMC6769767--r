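gene	timepoint	vaf
ERBB4	diagnosis	0.0075
FLT4	diagnosis	0.0066
U933G03	diagnosis	0.0088
U933G04	diagnosis	0.0068
U933G05	diagnosis	0.0031
U933G06	diagnosis	0.0043
U933G07	diagnosis	0.0076
U933G08	diagnosis	0.0082
U933G09	diagnosis	0.0075
U933G10	diagnosis	0.0044
U933G11	diagnosis	0.0066
U933G12	diagnosis	0.0049
U933G13	diagnosis	0.0033
U933G14	diagnosis	0.0089
U933G15	diagnosis	0.0069
U933G16	diagnosis	0.005
U933G17	diagnosis	0.0045
U933G18	diagnosis	0.0068
ERBB4	relapse	0.308
FLT4	relapse	0.378
U933G03	relapse	0.305
U933G04	relapse	0.375
U933G05	relapse	0.313
U933G06	relapse	0.374
U933G07	relapse	0.387
U933G08	relapse	0.331
U933G09	relapse	0.399
U933G10	relapse	0.321
U933G11	relapse	0.361
U933G12	relapse	0.307
U933G13	relapse	0.373
U933G14	relapse	0.385
U933G15	relapse	0.361
U933G16	relapse	0.325
U933G17	relapse	0.366
U933G18	relapse	0.36
ETV6	relapse	0.34
TMEM117	relapse	0.37
DNMT3A	diagnosis	0.46
NPM1	diagnosis	0.44
IDH1	diagnosis	0.4
FLT3	diagnosis	0.43
DNMT3A	relapse	0.42
NPM1	relapse	0.41
FLT3	relapse	0.05
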