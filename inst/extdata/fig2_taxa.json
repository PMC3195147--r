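{
  "sides": {
    "Capsaspora": "UNIKONT",
    "Choanoflagellata": "UNIKONT",
    "Metazoa": "UNIKONT",
    "Dikarya": "UNIKONT",
    "Chytridiomycota": "UNIKONT",
    "Microsporidia": "UNIKONT",
    "Apusozoa": "UNIKONT",
    "Amoebozoa": "UNIKONT",
    "Excavata": "BIKONT",
    "Apicomplexa": "BIKONT",
    "Ciliata": "BIKONT",
    "Heterokonta": "BIKONT",
    "Haptophyta": "BIKONT",
    "Viridiplantae": "BIKONT",
    "Rhodophyta": "BIKONT"
  }
}
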