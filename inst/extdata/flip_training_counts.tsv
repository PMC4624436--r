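# Peptide-flip training-set composition by geometry cluster, plus the
# background residue composition used for the glycine-enrichment test
# (6,092 glycines among 78,094 residues in 337 randomly selected chains).
# columns: cluster  n_examples  n_tight_turn  n_gly_first  n_gly_second
tweaked_down	26	13	0	16
simple_down	29	12	4	19
left	10	0	1	2
right	14	2	1	3
background	78094	NA	NA	6092
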