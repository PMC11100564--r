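# Carbon atoms per amino-acid molecule, used to normalise hydrolyzable
# amino-acid concentrations to micromoles of carbon. Standard stoichiometry;
# includes the non-protein acids GABA (gamma-aminobutyric acid) and 2-AAA
# (2-aminoadipic acid) that appear in sediment hydrolysates.
aa_code	carbon_atoms
Gly	2
Ala	3
Ser	3
Cys	3
Asp	4
Thr	4
GABA	4
Pro	5
Glu	5
Val	5
Met	5
2-AAA	6
Ile	6
Leu	6
Lys	6
His	6
Arg	6
Phe	9
Tyr	9
Trp	11
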