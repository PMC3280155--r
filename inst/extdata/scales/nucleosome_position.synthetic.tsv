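# nucleosome position: trinucleotide nucleosome-occupancy preference,
# dimensionless; SYNTHETIC STAND-IN for parameters derived from in vivo
# nucleosome maps (shipped as a constant table, never re-derived here)
kmer	value
AAA	-0.418
AAC	-0.009
AAG	-0.038
AAT	-0.361
ACA	-0.077
ACC	0.039
ACG	0.072
ACT	-0.070
AGA	-0.068
AGC	0.059
AGG	0.082
AGT	-0.060
ATA	-0.414
ATC	-0.020
ATG	-0.046
ATT	-0.364
CAA	-0.035
CAC	0.079
CAG	0.092
CAT	-0.089
CCA	0.037
CCC	0.121
CCG	0.192
CCT	0.056
CGA	0.045
CGC	0.159
CGG	0.148
CGT	0.025
CTA	-0.057
CTC	0.036
CTG	0.004
CTT	-0.009
GAA	-0.028
GAC	0.066
GAG	0.064
GAT	-0.076
GCA	0.061
GCC	0.156
GCG	0.195
GCT	0.000
GGA	0.005
GGC	0.174
GGG	0.154
GGT	0.038
GTA	-0.031
GTC	0.097
GTG	0.087
GTT	-0.085
TAA	-0.368
TAC	-0.098
TAG	-0.009
TAT	-0.446
TCA	-0.072
TCC	0.012
TCG	0.044
TCT	-0.073
TGA	-0.026
TGC	0.005
TGG	0.002
TGT	-0.078
TTA	-0.358
TTC	-0.004
TTG	-0.087
TTT	-0.430
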