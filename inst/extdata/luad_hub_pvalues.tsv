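gene	p_value
TEK	8.90e-10
ANGPT1	4.30e-05
CAV1	4.90e-05
SPP1	0.0015
CDH5	0.0034
PECAM1	0.0036
CLDN5	0.045
AGTR1	0.054
GJA4	0.13
FABP4	0.25
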