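{
  "description": "Frozen synthetic validation fixture: 4 x 20-residue tetramer, 2 planted sites, 24 lipids. Regenerate with simulateLipidTrajectory( syntheticSystemSpec(nFrames = 2000L, seed = 42L))",
  "nSubunits": 4,
  "residuesPerSubunit": 20,
  "residueSpacing": 7,
  "box": [200, 200, 60],
  "nLipidsPerSpecies": {
    "LIN": 12,
    "STE": 12
  },
  "outerPerSpecies": {
    "LIN": 8,
    "STE": 8
  },
  "leafletOffset": 17,
  "pinOffset": 2.5,
  "pinZ": 1.5,
  "diffusionSigma": 3,
  "nFrames": 2000,
  "dt": 0.5,
  "seed": 42,
  "sites": [
    {
      "siteId": "I",
      "anchorPosition": 5,
      "captureRadius": 5,
      "pOn": {
        "LIN": 0.15,
        "STE": 0.05
      },
      "kOff": {
        "LIN": 0.05,
        "STE": 0.05
      }
    },
    {
      "siteId": "II",
      "anchorPosition": 13,
      "captureRadius": 5,
      "pOn": {
        "LIN": 0.15,
        "STE": 0.05
      },
      "kOff": {
        "LIN": 0.05,
        "STE": 0.05
      }
    }
  ],
  "permanentBinder": true,
  "groundTruth": {
    "siteResidues": {
      "I": [5, 25, 45, 65],
      "II": [13, 33, 53, 73]
    },
    "permanentLipidMolid": 5,
    "meanDwellFrames": 20
  }
}
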