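{
  "variant": "g.4789T>C",
  "reference_id": "D0003",
  "origin": "genetic",
  "protein_change": [
    "L",
    "P"
  ],
  "reference_states": {
    "DNA": "IDbase:D0003",
    "RNA": "IDbase:C0003",
    "protein": "UniProt:O43918"
  },
  "ontology_version": "variotools-mini/1.0",
  "effects": [
    {
      "concept": "effect on protein information transfer",
      "level": "protein"
    },
    {
      "concept": "effect on alpha helix",
      "level": "protein"
    },
    {
      "concept": "protein conformational change",
      "level": "protein"
    },
    {
      "concept": "association of protein variation to pathogenicity",
      "level": "protein",
      "pathogenicity": "disease_causing"
    },
    {
      "concept": "effect on protein activity",
      "level": "protein",
      "quantity": "missing",
      "evidence": "reporter gene assay"
    },
    {
      "concept": "effect on protein interaction",
      "level": "protein",
      "quantity": "missing",
      "interaction_attributes": [
        "protein",
        "protein complex"
      ],
      "evidence": "gel filtration"
    },
    {
      "concept": "effect on protein subcellular localization",
      "level": "protein",
      "evidence": "immunofluorescence"
    }
  ]
}
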