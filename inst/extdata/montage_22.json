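{
  "description": "Mapping from 22-electrode recording channel index to 10-10 system labels (motor-cortex montage).",
  "labels": ["Fz", "FC3", "FC1", "FCz", "FC2", "FC4", "C5", "C3", "C1",
             "Cz", "C2", "C4", "C6", "CP3", "CP1", "CPz", "CP2", "CP4",
             "P1", "Pz", "P2", "POz"]
}
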