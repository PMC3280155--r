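# bendability: trinucleotide DNase-I/nucleosome bendability, dimensionless
# SYNTHETIC STAND-IN: A-tract triplets rigid, GC-containing flexible,
# fixed jitter; not the published trinucleotide measurements
kmer	value
AAA	-0.096
AAC	0.117
AAG	0.150
AAT	-0.137
ACA	0.167
ACC	0.214
ACG	0.223
ACT	0.108
AGA	0.149
AGC	0.252
AGG	0.234
AGT	0.095
ATA	-0.078
ATC	0.154
ATG	0.164
ATT	-0.066
CAA	0.097
CAC	0.233
CAG	0.193
CAT	0.111
CCA	0.246
CCC	0.323
CCG	0.331
CCT	0.203
CGA	0.254
CGC	0.302
CGG	0.329
CGT	0.242
CTA	0.160
CTC	0.200
CTG	0.207
CTT	0.137
GAA	0.124
GAC	0.254
GAG	0.191
GAT	0.133
GCA	0.210
GCC	0.275
GCG	0.282
GCT	0.255
GGA	0.179
GGC	0.274
GGG	0.307
GGT	0.212
GTA	0.125
GTC	0.235
GTG	0.251
GTT	0.094
TAA	-0.133
TAC	0.113
TAG	0.141
TAT	-0.108
TCA	0.124
TCC	0.192
TCG	0.236
TCT	0.105
TGA	0.133
TGC	0.257
TGG	0.207
TGT	0.097
TTA	-0.122
TTC	0.101
TTG	0.137
TTT	-0.126
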