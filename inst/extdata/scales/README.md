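# Bundled structural-property conversion schemas

Format: TSV, `#` comment header lines, then `kmer<TAB>value`, one row per
k-mer; all 4^k k-mers over {A,C,G,T} must be present (k = 2 or 3).
`index.tsv` lists the thirteen features in the fixed order that defines
the dimension numbering of the concatenated feature space, with `k`,
file name and provenance.

Provenance:

* `provenance = published` — transcribed from the classic biophysical
  dinucleotide scales named in each file's header (SantaLucia duplex free
  energy, Ornstein stacking energy, Breslauer duplex disrupt energy, Ho
  Z-DNA, Sivolob & Khrapunov bending stiffness, el Hassan & Calladine
  propeller twist, Olson protein-DNA twist).
* `provenance = synthetic` (`*.synthetic.tsv`) — deterministic stand-ins
  generated by `data-raw/make_scales.R` (fixed seed): plausible in units,
  sign and AT/GC ordering, NOT the published measurements. The
  nucleosome-position table is a constant stand-in by design (derived
  in vivo parameters are out of scope here).

All pipeline code is scale-agnostic: replace any file with a corrected
table (same format) and rerun; `load_scale()` validates completeness.
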