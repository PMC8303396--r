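{
  "_comment": "SYNTHETIC placeholder coefficients for exercising the variance-model solver; not measured values. Supply your own (M1, M2, M3) per cone type.",
  "green": [0.766, 0.0, 0.0],
  "red": [0.595, 0.0, 0.0],
  "blue": [0.571, 0.0, 0.0],
  "violet": [0.416, 0.0, 0.0],
  "double": [1.455, 0.0, 0.0]
}
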