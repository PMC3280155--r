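# protein deformation: deformability upon protein binding, dimensionless
# SYNTHETIC STAND-IN: fixed-seed draw on a plausible range
kmer	value
AA	6.24
AC	3.08
AG	8.71
AT	8.64
CA	8.21
CC	7.34
CG	5.24
CT	3.46
GA	5.00
GC	4.68
GG	5.32
GT	4.85
TA	3.21
TC	3.80
TG	3.83
TT	4.76
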