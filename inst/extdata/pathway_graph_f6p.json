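{
  "origin": "F6P",
  "metabolites": [
    {"id": "F6P", "label": "fructose-6-phosphate (common origin)"},
    {"id": "G3P", "label": "glycerate-3-phosphate"},
    {"id": "PEP", "label": "phosphoenolpyruvate"},
    {"id": "Pyrv", "label": "pyruvate"},
    {"id": "AcCoA", "label": "acetyl-CoA (citric-acid-cycle entry)"},
    {"id": "TCA", "label": "citric-acid cycle (completed 8-enzyme circuit)"},
    {"id": "OXA", "label": "oxaloacetate (TCA port)"},
    {"id": "2OG", "label": "2-oxoglutarate (TCA port)"},
    {"id": "PPPcore", "label": "pentose phosphate pathway core (9-enzyme fused circuit)"},
    {"id": "E4P", "label": "erythrose-4-phosphate (PPP-core port)"},
    {"id": "R5P", "label": "ribose-5-phosphate (PPP-core port)"},
    {"id": "PRPP", "label": "5-phospho-alpha-D-ribose-1-diphosphate"},
    {"id": "Cr", "label": "chorismate"},
    {"id": "Ser", "label": "serine"},
    {"id": "Gly", "label": "glycine"},
    {"id": "Ala", "label": "alanine"},
    {"id": "Cys", "label": "cysteine"},
    {"id": "Thr", "label": "threonine"},
    {"id": "Val", "label": "valine"},
    {"id": "Leu", "label": "leucine"},
    {"id": "Ile", "label": "isoleucine"},
    {"id": "Asp", "label": "aspartate"},
    {"id": "Asn", "label": "asparagine"},
    {"id": "Met", "label": "methionine"},
    {"id": "Lys", "label": "lysine"},
    {"id": "Glu", "label": "glutamate"},
    {"id": "Gln", "label": "glutamine"},
    {"id": "Pro", "label": "proline"},
    {"id": "Arg", "label": "arginine"},
    {"id": "Phe", "label": "phenylalanine"},
    {"id": "Tyr", "label": "tyrosine"},
    {"id": "Trp", "label": "tryptophan"},
    {"id": "His", "label": "histidine"}
  ],
  "local_paths": [
    {"source": "F6P", "target": "G3P", "delta_ne": 4,
     "enzymes": ["6-phosphofructokinase 1", "fructose-bisphosphate aldolase I",
                 "glyceraldehyde 3-phosphate dehydrogenase", "phosphoglycerate kinase"]},
    {"source": "G3P", "target": "PEP", "delta_ne": 2,
     "enzymes": ["2,3-bisphosphoglycerate-dependent phosphoglycerate mutase", "enolase"]},
    {"source": "PEP", "target": "Pyrv", "delta_ne": 1,
     "enzymes": ["pyruvate kinase"]},
    {"source": "G3P", "target": "Ser", "delta_ne": 3,
     "enzymes": ["phosphoglycerate dehydrogenase", "phosphoserine transaminase",
                 "phosphoserine phosphatase"]},
    {"source": "Ser", "target": "Gly", "delta_ne": 1,
     "enzymes": ["serine hydroxymethyltransferase"]},
    {"source": "Ser", "target": "Cys", "delta_ne": 2,
     "enzymes": ["serine acetyltransferase", "cysteine synthase"]},
    {"source": "Gly", "target": "Thr", "delta_ne": 1},
    {"source": "Thr", "target": "Ile", "delta_ne": 5},
    {"source": "Pyrv", "target": "Ala", "delta_ne": 1,
     "enzymes": ["alanine transaminase"]},
    {"source": "Pyrv", "target": "Val", "delta_ne": 4},
    {"source": "Pyrv", "target": "Leu", "delta_ne": 8},
    {"source": "Pyrv", "target": "AcCoA", "delta_ne": 1,
     "enzymes": ["pyruvate dehydrogenase complex"]},
    {"source": "AcCoA", "target": "TCA", "delta_ne": 8, "circuit_tag": "TCA",
     "enzymes": ["citrate synthase", "aconitase", "isocitrate dehydrogenase",
                 "alpha-ketoglutarate dehydrogenase", "succinyl-CoA synthetase",
                 "succinate dehydrogenase", "fumarase", "malate dehydrogenase"]},
    {"source": "TCA", "target": "OXA", "delta_ne": 0},
    {"source": "TCA", "target": "2OG", "delta_ne": 0},
    {"source": "OXA", "target": "Asp", "delta_ne": 1,
     "enzymes": ["aspartate transaminase"]},
    {"source": "Asp", "target": "Asn", "delta_ne": 1,
     "enzymes": ["asparagine synthetase"]},
    {"source": "Asp", "target": "Met", "delta_ne": 8},
    {"source": "Asp", "target": "Lys", "delta_ne": 8},
    {"source": "2OG", "target": "Glu", "delta_ne": 1,
     "enzymes": ["glutamate dehydrogenase"]},
    {"source": "Glu", "target": "Gln", "delta_ne": 1,
     "enzymes": ["glutamine synthetase"]},
    {"source": "Glu", "target": "Pro", "delta_ne": 3, "spontaneous_steps": 1},
    {"source": "Glu", "target": "Arg", "delta_ne": 8, "circuit_tag": "UCycle"},
    {"source": "F6P", "target": "PPPcore", "delta_ne": 9, "circuit_tag": "PPPcore"},
    {"source": "PPPcore", "target": "E4P", "delta_ne": 0},
    {"source": "PPPcore", "target": "R5P", "delta_ne": 0},
    {"source": "R5P", "target": "PRPP", "delta_ne": 1,
     "enzymes": ["ribose-phosphate pyrophosphokinase"]},
    {"source": "E4P", "target": "Cr", "delta_ne": 7},
    {"source": "Cr", "target": "Phe", "delta_ne": 3},
    {"source": "Cr", "target": "Tyr", "delta_ne": 3},
    {"source": "Cr", "target": "Trp", "delta_ne": 5},
    {"source": "PPPcore", "target": "His", "delta_ne": 10},
    {"source": "F6P", "target": "E4P", "delta_ne": 2, "is_bypass": true},
    {"source": "Ser", "target": "Pyrv", "delta_ne": 1, "is_bypass": true}
  ]
}
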