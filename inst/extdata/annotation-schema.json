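{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "molshots offline annotation file",
  "description": "One JSON object bundling the per-entry annotation payloads in the same shapes as the public PDBe API endpoints. Every section is optional; unknown keys are ignored. Each section may either hold the payload directly or wrap it under a single entry-id key, as the live API does.",
  "type": "object",
  "properties": {
    "molecules": {
      "description": "Entity names (endpoint pdb/entry/molecules/{id}). Array of molecule records.",
      "type": ["array", "object"],
      "items": {
        "type": "object",
        "properties": {
          "entity_id": {"type": ["string", "integer"]},
          "molecule_name": {"type": "array", "items": {"type": "string"}}
        },
        "required": ["entity_id"]
      }
    },
    "summary": {
      "description": "Entry summary with the preferred assembly (endpoint pdb/entry/summary/{id}).",
      "type": ["array", "object"],
      "items": {
        "type": "object",
        "properties": {
          "assemblies": {
            "type": "array",
            "items": {
              "type": "object",
              "properties": {
                "assembly_id": {"type": ["string", "integer"]},
                "preferred": {"type": "boolean"},
                "preferred_assembly": {"type": "boolean"}
              }
            }
          }
        }
      }
    },
    "modified_residues": {
      "description": "Modified residue sites (endpoint pdb/entry/modified_AA_or_NA/{id}).",
      "type": ["array", "object"],
      "items": {
        "type": "object",
        "properties": {
          "chem_comp_id": {"type": "string"},
          "chain_id": {"type": "string"},
          "author_residue_number": {"type": "integer"}
        },
        "required": ["chem_comp_id", "chain_id", "author_residue_number"]
      }
    },
    "mappings": {
      "description": "SIFTS domain mappings (endpoints mappings/{id}, nucleic_mappings/{id}). Keys are resource names (CATH, SCOP, Pfam, Rfam); each maps family id to {mappings: [segment]}.",
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "additionalProperties": {
          "type": "object",
          "properties": {
            "mappings": {
              "type": "array",
              "items": {
                "type": "object",
                "properties": {
                  "chain_id": {"type": "string"},
                  "start": {"type": "object", "properties": {"author_residue_number": {"type": "integer"}}},
                  "end": {"type": "object", "properties": {"author_residue_number": {"type": "integer"}}}
                }
              }
            }
          }
        }
      }
    },
    "validation": {
      "description": "Residue-wise outlier summary (endpoint validation/residuewise_outlier_summary/entry/{id}). The outlier count of a residue is the length of its outlier_types array.",
      "type": "object",
      "properties": {
        "molecules": {
          "type": "array",
          "items": {
            "type": "object",
            "properties": {
              "chains": {
                "type": "array",
                "items": {
                  "type": "object",
                  "properties": {
                    "chain_id": {"type": "string"},
                    "models": {
                      "type": "array",
                      "items": {
                        "type": "object",
                        "properties": {
                          "residues": {
                            "type": "array",
                            "items": {
                              "type": "object",
                              "properties": {
                                "author_residue_number": {"type": "integer"},
                                "outlier_types": {"type": "array", "items": {"type": "string"}}
                              }
                            }
                          }
                        }
                      }
                    }
                  }
                }
              }
            }
          }
        }
      }
    }
  }
}
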