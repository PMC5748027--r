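# Substructural series tracked among final multi-target candidates.
# Each entry: a display name and the SMARTS defining the series core.
- name: triazoloquinazoline
  smarts: "c1ccc2c(c1)c1ncnn1cn2"
- name: imidazoquinoxaline
  smarts: "c1ccc2c(c1)n1cncc1cn2"
- name: alkoxyisoquinoline
  smarts: "[#6][OX2]c1cc2ccncc2cc1[OX2][#6]"
- name: aminopyridine_carbonitrile
  smarts: "[NX3H2]c1ncccc1C#N"
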