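{
  "ontology_version": "variotools-mini/1.0",
  "variant": {
    "hgvs": "g.4789T>C",
    "reference_id": "D0003"
  },
  "levels_affected": [
    "DNA",
    "RNA",
    "protein"
  ],
  "reference_states": {
    "DNA": "IDbase:D0003",
    "RNA": "IDbase:C0003",
    "protein": "UniProt:O43918"
  },
  "annotations": [
    {
      "level": "DNA",
      "path": [
        "VariO:0128",
        "VariO:0129",
        "VariO:0322",
        "VariO:0135",
        "VariO:0136",
        "VariO:0313",
        "VariO:0314"
      ],
      "ambiguous_path": false,
      "extra_terms": [],
      "attributes": [],
      "evidence": [],
      "references": []
    },
    {
      "level": "DNA",
      "path": [
        "VariO:0128",
        "VariO:0129",
        "VariO:0127",
        "VariO:0130"
      ],
      "ambiguous_path": false,
      "extra_terms": [],
      "attributes": [],
      "evidence": [],
      "references": []
    },
    {
      "level": "RNA",
      "path": [
        "VariO:0297",
        "VariO:0306",
        "VariO:0328",
        "VariO:0312",
        "VariO:0313",
        "VariO:0314"
      ],
      "ambiguous_path": false,
      "extra_terms": [
        "VariO:0308"
      ],
      "attributes": [],
      "evidence": [],
      "references": []
    },
    {
      "level": "protein",
      "path": [
        "VariO:0002",
        "VariO:0012",
        "VariO:0325",
        "VariO:0021"
      ],
      "ambiguous_path": false,
      "extra_terms": [],
      "attributes": [],
      "evidence": [],
      "references": []
    },
    {
      "level": "protein",
      "path": [
        "VariO:0002",
        "VariO:0323",
        "VariO:0013"
      ],
      "ambiguous_path": false,
      "extra_terms": [],
      "attributes": [],
      "evidence": [],
      "references": []
    },
    {
      "level": "protein",
      "path": [
        "VariO:0002",
        "VariO:0003",
        "VariO:0011"
      ],
      "ambiguous_path": false,
      "extra_terms": [],
      "attributes": [],
      "evidence": [],
      "references": []
    },
    {
      "level": "protein",
      "path": [
        "VariO:0002",
        "VariO:0060",
        "VariO:0064",
        "VariO:0070",
        "VariO:0079",
        "VariO:0080",
        "VariO:0082",
        "VariO:0085"
      ],
      "ambiguous_path": false,
      "extra_terms": [],
      "attributes": [],
      "evidence": [],
      "references": []
    },
    {
      "level": "protein",
      "path": [
        "VariO:0002",
        "VariO:0060",
        "VariO:0064",
        "VariO:0070",
        "VariO:0073",
        "VariO:0074"
      ],
      "ambiguous_path": false,
      "extra_terms": [],
      "attributes": [],
      "evidence": [],
      "references": []
    },
    {
      "level": "protein",
      "path": [
        "VariO:0002",
        "VariO:0032",
        "VariO:0047"
      ],
      "ambiguous_path": false,
      "extra_terms": [],
      "attributes": [
        {
          "attribute_id": "VariO:0294",
          "modified_term_id": "VariO:0047",
          "full_path": null
        }
      ],
      "evidence": [],
      "references": []
    },
    {
      "level": "protein",
      "path": [
        "VariO:0002",
        "VariO:0032",
        "VariO:0053"
      ],
      "ambiguous_path": false,
      "extra_terms": [],
      "attributes": [
        {
          "attribute_id": "VariO:0292",
          "modified_term_id": "VariO:0053",
          "full_path": null
        }
      ],
      "evidence": [
        {
          "eco_id": "ECO:0000049",
          "eco_name": "reporter gene assay evidence",
          "linked_term_id": "VariO:0053"
        }
      ],
      "references": []
    },
    {
      "level": "protein",
      "path": [
        "VariO:0002",
        "VariO:0032",
        "VariO:0058"
      ],
      "ambiguous_path": false,
      "extra_terms": [],
      "attributes": [
        {
          "attribute_id": "VariO:0292",
          "modified_term_id": "VariO:0058",
          "full_path": null
        },
        {
          "attribute_id": "VariO:0277",
          "modified_term_id": "VariO:0058",
          "full_path": [
            "VariO:0232",
            "VariO:0236",
            "VariO:0262",
            "VariO:0273",
            "VariO:0277"
          ]
        },
        {
          "attribute_id": "VariO:0269",
          "modified_term_id": "VariO:0058",
          "full_path": [
            "VariO:0232",
            "VariO:0236",
            "VariO:0262",
            "VariO:0267",
            "VariO:0269"
          ]
        }
      ],
      "evidence": [
        {
          "eco_id": "ECO:0000156",
          "eco_name": "protein separation evidence",
          "linked_term_id": "VariO:0058"
        }
      ],
      "references": []
    },
    {
      "level": "protein",
      "path": [
        "VariO:0002",
        "VariO:0032",
        "VariO:0033"
      ],
      "ambiguous_path": false,
      "extra_terms": [],
      "attributes": [],
      "evidence": [
        {
          "eco_id": "ECO:0000007",
          "eco_name": "immunofluorescence evidence",
          "linked_term_id": "VariO:0033"
        }
      ],
      "references": []
    }
  ]
}
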