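Bradyrhizobium
Ralstonia
Burkholderia
Methylobacterium
Sphingomonas
Propionibacterium
Cutibacterium
Acinetobacter
Pseudomonas
Stenotrophomonas
Delftia
Herbaspirillum
Comamonas
Mesorhizobium
Rhizobium
Phyllobacterium
Afipia
Ochrobactrum
Novosphingobium
Sphingobium
Caulobacter
Brevundimonas
Pelomonas
Cupriavidus
Variovorax
Curvibacter
Undibacterium
Duganella
Massilia
Janthinobacterium
Micrococcus
Kocuria
Rhodococcus
Corynebacterium
Dietzia
Geodermatophilus
Deinococcus
Thermus
Paenibacillus
Brevibacillus
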