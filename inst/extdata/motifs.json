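{
  "version": "1.1",
  "comment": "SAR motif catalog: SMARTS pattern and a canonical exemplar molecule for each named substructure class. Aromatic nitrogens are written without H constraints so N-substituted ring variants still count.",
  "motifs": {
    "benzodioxole": {"smarts": "c1ccc2OCOc2c1", "exemplar": "c1ccc2OCOc2c1"},
    "pyridine":     {"smarts": "c1ccncc1",      "exemplar": "c1ccncc1"},
    "indole":       {"smarts": "c1ccc2c(c1)ccn2", "exemplar": "c1ccc2c(c1)cc[nH]2"},
    "imidazole":    {"smarts": "c1cncn1",       "exemplar": "c1c[nH]cn1"},
    "piperidine":   {"smarts": "C1CCNCC1",      "exemplar": "C1CCNCC1"},
    "pyrazine":     {"smarts": "c1cnccn1",      "exemplar": "c1cnccn1"},
    "triazole":     {"smarts": "c1ncnn1",       "exemplar": "c1nc[nH]n1"},
    "heterocyclic_nitrogen": {"smarts": "[#7;R]", "exemplar": "c1ccncc1"},
    "coordinating_heteroatom": {"smarts": "[#7,#8,#16]", "exemplar": "CCO"}
  }
}
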