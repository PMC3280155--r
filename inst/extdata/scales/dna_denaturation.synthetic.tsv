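# DNA denaturation: melting-temperature-like stability, degrees C
# SYNTHETIC STAND-IN: affine map of the SantaLucia dG scale plus fixed
# jitter; not the published denaturation measurements
kmer	value
AA	49.73
AC	66.08
AG	59.08
AT	45.06
CA	67.59
CC	79.85
CG	92.26
CT	60.89
GA	61.42
GC	94.85
GG	80.42
GT	67.24
TA	35.90
TC	62.46
TG	67.36
TT	49.52
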