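{
  "id": "water_fse",
  "phantom": {
    "type": "cylindrical",
    "matrixSize": 256,
    "diameter": 100,
    "pixelSize": 1,
    "sliceThickness": 5,
    "tissue": { "t1": 3505, "t2": 2390, "d": 0.0021, "protonDensity": 1 }
  },
  "sequence": {
    "tr": 8000, "te": 29, "bValue": 0,
    "nChannels": 16, "noiseSigma": 1
  },
  "noise": { "te": 275, "bValue": 18000 },
  "amplitude": 10,
  "nRepeats": 2,
  "seed": 1
}
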