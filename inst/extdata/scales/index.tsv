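feature	k	file	provenance
a_philicity	2	a_philicity.synthetic.tsv	synthetic
b_dna_twist	2	b_dna_twist.synthetic.tsv	synthetic
bendability	3	bendability.synthetic.tsv	synthetic
stacking_energy	2	stacking_energy.tsv	published
dna_bending_stiffness	2	dna_bending_stiffness.tsv	published
dna_denaturation	2	dna_denaturation.synthetic.tsv	synthetic
duplex_free_energy	2	duplex_free_energy.tsv	published
duplex_disrupt_energy	2	duplex_disrupt_energy.tsv	published
nucleosome_position	3	nucleosome_position.synthetic.tsv	synthetic
propeller_twist	2	propeller_twist.tsv	published
protein_deformation	2	protein_deformation.synthetic.tsv	synthetic
protein_dna_twist	2	protein_dna_twist.tsv	published
z_dna	2	z_dna.tsv	published
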