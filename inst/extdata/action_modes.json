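{
  "agonist": 1,
  "partial agonist": 1,
  "activator": 1,
  "stimulator": 1,
  "inducer": 1,
  "positive allosteric modulator": 1,
  "potentiator": 1,
  "positive modulator": 1,
  "inhibitor": -1,
  "inhibitory allosteric modulator": -1,
  "inhibitor competitive": -1,
  "antagonist": -1,
  "partial antagonist": -1,
  "negative modulator": -1,
  "inverse agonist": -1,
  "blocker": -1,
  "suppressor": -1,
  "desensitize the target": -1,
  "neutralizer": -1,
  "reducer": -1,
  "antibody": 0,
  "cofactor": 0,
  "modulator": 0,
  "binder": 0,
  "chaperone": 0,
  "cleavage": 0,
  "metabolizer": 0,
  "ligand": 0,
  "product of": 0,
  "component of": 0,
  "chelator": 0,
  "cross-linking/alkylation": 0,
  "intercalation": 0,
  "adduct": 0,
  "acetylation": 0,
  "allosteric modulator": 0
}
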