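# A-philicity: propensity to adopt the A-form helix, dimensionless
# SYNTHETIC STAND-IN: GC-driven surrogate with fixed jitter
kmer	value
AA	0.107
AC	0.586
AG	0.476
AT	0.224
CA	0.491
CC	1.091
CG	0.911
CT	0.584
GA	0.675
GC	1.089
GG	1.036
GT	0.589
TA	0.081
TC	0.653
TG	0.642
TT	0.217
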