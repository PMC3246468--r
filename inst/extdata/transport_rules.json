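{
  "comment": "Substrate-matching rules linking repertoire systems to boundary-compound classes. 'classes' match any compound of the class; 'compounds' match named substrates only. level 'general' marks broad channels/exporters whose class coverage is enumerated explicitly.",
  "rules": [
    {"system_id": "OmpF", "classes": ["ion", "small_solute", "amino_acid", "organic_acid", "nucleotide_or_derivative", "sugar_or_derivative", "vitamin_or_cofactor", "misc"], "compounds": [], "level": "general", "directions": ["import", "export"], "membrane": "outer"},
    {"system_id": "OmpA", "classes": ["ion", "small_solute"], "compounds": [], "level": "general", "directions": ["import", "export"], "membrane": "outer"},
    {"system_id": "GlpF", "classes": ["small_solute"], "compounds": [], "level": "specific", "directions": ["import", "export"], "membrane": "inner"},
    {"system_id": "YggB", "classes": ["ion"], "compounds": [], "level": "general", "directions": ["export"], "membrane": "inner"},
    {"system_id": "PitA", "classes": [], "compounds": ["phosphate"], "level": "specific", "directions": ["import"], "membrane": "inner"},
    {"system_id": "Znu", "classes": [], "compounds": ["zinc"], "level": "specific", "directions": ["import"], "membrane": "inner"},
    {"system_id": "YbeX", "classes": [], "compounds": ["magnesium", "cobalt"], "level": "specific", "directions": ["export"], "membrane": "inner"},
    {"system_id": "YoaE", "classes": [], "compounds": ["magnesium", "cobalt"], "level": "specific", "directions": ["export"], "membrane": "inner"},
    {"system_id": "Atp", "classes": [], "compounds": ["proton"], "level": "specific", "directions": ["export"], "membrane": "inner"},
    {"system_id": "PtsG", "classes": ["sugar_or_derivative"], "compounds": [], "level": "specific", "directions": ["import"], "membrane": "inner"},
    {"system_id": "MtlA", "classes": ["sugar_or_derivative"], "compounds": [], "level": "specific", "directions": ["import"], "membrane": "inner"},
    {"system_id": "YchE", "classes": ["amino_acid"], "compounds": [], "level": "specific", "directions": ["import"], "membrane": "inner"},
    {"system_id": "YhgN", "classes": ["amino_acid"], "compounds": [], "level": "specific", "directions": ["import"], "membrane": "inner"},
    {"system_id": "YajR", "classes": ["amino_acid", "organic_acid", "nucleotide_or_derivative", "vitamin_or_cofactor"], "compounds": [], "level": "general", "directions": ["export"], "membrane": "inner"},
    {"system_id": "TsgA", "classes": ["amino_acid", "organic_acid", "nucleotide_or_derivative", "vitamin_or_cofactor", "sugar_or_derivative"], "compounds": [], "level": "general", "directions": ["export"], "membrane": "inner"},
    {"system_id": "YnfM", "classes": ["amino_acid", "organic_acid", "nucleotide_or_derivative", "vitamin_or_cofactor", "sugar_or_derivative"], "compounds": [], "level": "general", "directions": ["export"], "membrane": "inner"},
    {"system_id": "YabI", "classes": ["amino_acid", "organic_acid", "nucleotide_or_derivative", "vitamin_or_cofactor"], "compounds": [], "level": "general", "directions": ["export"], "membrane": "inner"},
    {"system_id": "YgjT", "classes": ["sugar_or_derivative"], "compounds": [], "level": "specific", "directions": ["import", "export"], "membrane": "inner"},
    {"system_id": "PagO", "classes": ["amino_acid", "organic_acid"], "compounds": [], "level": "specific", "directions": ["export"], "membrane": "inner"},
    {"system_id": "YdiK", "classes": ["amino_acid", "organic_acid", "nucleotide_or_derivative", "vitamin_or_cofactor", "small_solute"], "compounds": [], "level": "general", "directions": ["export"], "membrane": "inner"},
    {"system_id": "Mdl", "classes": ["amino_acid", "organic_acid", "nucleotide_or_derivative", "vitamin_or_cofactor", "lipid", "misc"], "compounds": [], "level": "general", "directions": ["export"], "membrane": "inner"},
    {"system_id": "MviN", "classes": ["lipid"], "compounds": [], "level": "specific", "directions": ["export"], "membrane": "inner"},
    {"system_id": "NorM", "classes": ["misc"], "compounds": [], "level": "general", "directions": ["export"], "membrane": "inner"},
    {"system_id": "Sec", "classes": ["peptide_or_protein"], "compounds": [], "level": "specific", "directions": ["export"], "membrane": "inner"},
    {"system_id": "T3", "classes": ["peptide_or_protein"], "compounds": [], "level": "specific", "directions": ["export"], "membrane": "inner"},
    {"system_id": "YidC", "classes": ["peptide_or_protein"], "compounds": [], "level": "specific", "directions": ["export"], "membrane": "inner"},
    {"system_id": "Lol", "classes": ["peptide_or_protein"], "compounds": [], "level": "specific", "directions": ["export"], "membrane": "inner"},
    {"system_id": "YfgM", "classes": ["peptide_or_protein"], "compounds": [], "level": "specific", "directions": ["export"], "membrane": "inner"},
    {"system_id": "YaeT", "classes": ["peptide_or_protein"], "compounds": [], "level": "specific", "directions": ["export"], "membrane": "outer"}
  ]
}
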