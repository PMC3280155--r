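# B-DNA twist: helical twist of B-form DNA, degrees
# SYNTHETIC STAND-IN: values near the canonical 34 degrees with fixed jitter
kmer	value
AA	30.37
AC	32.42
AG	33.89
AT	31.61
CA	33.59
CC	36.23
CG	35.16
CT	32.98
GA	33.10
GC	36.99
GG	37.59
GT	35.45
TA	31.42
TC	34.30
TG	32.54
TT	32.58
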