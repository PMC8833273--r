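{
  "id": "oil_ssepi",
  "phantom": {
    "type": "cylindrical",
    "matrixSize": 128,
    "diameter": 100,
    "pixelSize": 2,
    "sliceThickness": 5,
    "tissue": { "t1": 196, "t2": 75, "d": 4e-05, "protonDensity": 1 }
  },
  "sequence": {
    "tr": 3000, "te": 37, "bValue": 0,
    "nChannels": 16, "noiseSigma": 1
  },
  "noise": { "te": 500, "bValue": 18000 },
  "amplitude": 10,
  "nRepeats": 2,
  "seed": 1
}
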