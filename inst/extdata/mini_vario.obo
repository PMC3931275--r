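format-version: 1.2
data-version: variotools-mini/1.0

[Term]
id: VariO:0002
name: variation affecting protein

[Term]
id: VariO:0003
name: variation affecting protein function
is_a: VariO:0002 ! variation affecting protein

[Term]
id: VariO:0011
name: effect on protein information transfer
is_a: VariO:0003 ! variation affecting protein function

[Term]
id: VariO:0012
name: protein variation type
is_a: VariO:0002 ! variation affecting protein

[Term]
id: VariO:0013
name: protein variation of genetic origin
is_a: VariO:0323 ! protein variation origin

[Term]
id: VariO:0021
name: amino acid substitution
is_a: VariO:0325 ! protein variation classification

[Term]
id: VariO:0022
name: amino acid indel
is_a: VariO:0325 ! protein variation classification

[Term]
id: VariO:0024
name: variation emerging at protein level
is_a: VariO:0323 ! protein variation origin

[Term]
id: VariO:0032
name: variation affecting protein property
is_a: VariO:0002 ! variation affecting protein

[Term]
id: VariO:0033
name: effect on protein subcellular localization
is_a: VariO:0032 ! variation affecting protein property

[Term]
id: VariO:0047
name: association of protein variation to pathogenicity
is_a: VariO:0032 ! variation affecting protein property

[Term]
id: VariO:0053
name: effect on protein activity
is_a: VariO:0032 ! variation affecting protein property

[Term]
id: VariO:0058
name: effect on protein interaction
is_a: VariO:0032 ! variation affecting protein property

[Term]
id: VariO:0060
name: variation affecting protein structure
is_a: VariO:0002 ! variation affecting protein

[Term]
id: VariO:0064
name: effect on protein 3D structure
is_a: VariO:0060 ! variation affecting protein structure

[Term]
id: VariO:0070
name: effect on protein tertiary structure
is_a: VariO:0064 ! effect on protein 3D structure

[Term]
id: VariO:0073
name: effect on protein fold
is_a: VariO:0070 ! effect on protein tertiary structure

[Term]
id: VariO:0074
name: protein conformational change
is_a: VariO:0073 ! effect on protein fold

[Term]
id: VariO:0079
name: effect on protein secondary structural element
is_a: VariO:0070 ! effect on protein tertiary structure

[Term]
id: VariO:0080
name: effect on protein helix
is_a: VariO:0079 ! effect on protein secondary structural element

[Term]
id: VariO:0082
name: effect on right handed protein helix
is_a: VariO:0080 ! effect on protein helix

[Term]
id: VariO:0085
name: effect on alpha helix
is_a: VariO:0082 ! effect on right handed protein helix

[Term]
id: VariO:0127
name: DNA variation origin
is_a: VariO:0129 ! DNA variation type

[Term]
id: VariO:0128
name: variation affecting DNA

[Term]
id: VariO:0129
name: DNA variation type
is_a: VariO:0128 ! variation affecting DNA

[Term]
id: VariO:0130
name: DNA variation of genetic origin
is_a: VariO:0127 ! DNA variation origin

[Term]
id: VariO:0135
name: DNA chain variation
is_a: VariO:0322 ! DNA variation classification

[Term]
id: VariO:0136
name: DNA substitution
is_a: VariO:0135 ! DNA chain variation

[Term]
id: VariO:0140
name: not changed
is_a: VariO:9019 ! quantity change

[Term]
id: VariO:0146
name: DNA variation of non-genetic origin
is_a: VariO:0127 ! DNA variation origin

[Term]
id: VariO:0232
name: variation attribute

[Term]
id: VariO:0236
name: interaction
is_a: VariO:0232 ! variation attribute

[Term]
id: VariO:0262
name: interactor
is_a: VariO:0236 ! interaction

[Term]
id: VariO:0267
name: complex
is_a: VariO:0262 ! interactor

[Term]
id: VariO:0269
name: protein complex
is_a: VariO:0267 ! complex

[Term]
id: VariO:0273
name: biopolymer
is_a: VariO:0262 ! interactor

[Term]
id: VariO:0277
name: protein
is_a: VariO:0273 ! biopolymer

[Term]
id: VariO:0290
name: decreased
is_a: VariO:9019 ! quantity change

[Term]
id: VariO:0291
name: increased
is_a: VariO:9019 ! quantity change

[Term]
id: VariO:0292
name: missing
is_a: VariO:9019 ! quantity change

[Term]
id: VariO:0294
name: disease causing
is_a: VariO:9020 ! pathogenicity association

[Term]
id: VariO:0297
name: variation affecting RNA

[Term]
id: VariO:0306
name: RNA variation type
is_a: VariO:0297 ! variation affecting RNA

[Term]
id: VariO:0308
name: missense variation
is_a: VariO:0328 ! RNA variation classification
comment: lineage inferred; parent placement not printed

[Term]
id: VariO:0312
name: RNA substitution
is_a: VariO:0328 ! RNA variation classification

[Term]
id: VariO:0313
name: transition
is_a: VariO:0136 ! DNA substitution
is_a: VariO:0312 ! RNA substitution

[Term]
id: VariO:0314
name: pyrimidine transition
is_a: VariO:0313 ! transition

[Term]
id: VariO:0322
name: DNA variation classification
is_a: VariO:0129 ! DNA variation type

[Term]
id: VariO:0323
name: protein variation origin
is_a: VariO:0002 ! variation affecting protein

[Term]
id: VariO:0325
name: protein variation classification
is_a: VariO:0012 ! protein variation type

[Term]
id: VariO:0328
name: RNA variation classification
is_a: VariO:0306 ! RNA variation type

[Term]
id: VariO:0333
name: variation emerging at RNA level
is_a: VariO:9016 ! RNA variation origin

[Term]
id: VariO:9001
name: purine transition
is_a: VariO:0313 ! transition

[Term]
id: VariO:9002
name: transversion
is_a: VariO:0136 ! DNA substitution
is_a: VariO:0312 ! RNA substitution

[Term]
id: VariO:9003
name: synonymous variation
is_a: VariO:0328 ! RNA variation classification

[Term]
id: VariO:9004
name: nonsense variation
is_a: VariO:0328 ! RNA variation classification

[Term]
id: VariO:9005
name: DNA deletion
is_a: VariO:0135 ! DNA chain variation

[Term]
id: VariO:9006
name: DNA insertion
is_a: VariO:0135 ! DNA chain variation

[Term]
id: VariO:9007
name: DNA duplication
is_a: VariO:0135 ! DNA chain variation

[Term]
id: VariO:9008
name: DNA indel
is_a: VariO:0135 ! DNA chain variation

[Term]
id: VariO:9009
name: RNA deletion
is_a: VariO:0328 ! RNA variation classification

[Term]
id: VariO:9010
name: RNA insertion
is_a: VariO:0328 ! RNA variation classification

[Term]
id: VariO:9011
name: RNA duplication
is_a: VariO:0328 ! RNA variation classification

[Term]
id: VariO:9012
name: RNA indel
is_a: VariO:0328 ! RNA variation classification

[Term]
id: VariO:9013
name: amino acid deletion
is_a: VariO:0325 ! protein variation classification

[Term]
id: VariO:9014
name: amino acid insertion
is_a: VariO:0325 ! protein variation classification

[Term]
id: VariO:9015
name: amino acid duplication
is_a: VariO:0325 ! protein variation classification

[Term]
id: VariO:9016
name: RNA variation origin
is_a: VariO:0306 ! RNA variation type

[Term]
id: VariO:9017
name: RNA variation of genetic origin
is_a: VariO:9016 ! RNA variation origin

[Term]
id: VariO:9018
name: not disease causing
is_a: VariO:9020 ! pathogenicity association

[Term]
id: VariO:9019
name: quantity change
is_a: VariO:0232 ! variation attribute

[Term]
id: VariO:9020
name: pathogenicity association
is_a: VariO:0232 ! variation attribute

[Term]
id: VariO:9021
name: conservation
is_a: VariO:0232 ! variation attribute

[Term]
id: VariO:9022
name: conserved
is_a: VariO:9021 ! conservation

[Term]
id: VariO:9023
name: covariant
is_a: VariO:9021 ! conservation

[Term]
id: VariO:9024
name: nonconserved
is_a: VariO:9021 ! conservation
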