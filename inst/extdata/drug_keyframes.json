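{
  "comment": "Synthetic calibration keyframes: per-(drug, dose) landmark anchors (time_h, percent of pre-drug) for the force and cell-index channels, plus beat-duration widening and inter-beat jitter inflation profiles (time_h, multiplier). Doses are keyed in nmol/L. Values between anchors are obtained by monotone piecewise-cubic interpolation.",
  "verapamil": {
    "force": {
      "150": [[0, 100], [4, 85], [8, 100], [24, 100]],
      "300": [[0, 100], [12, 45], [24, 51]],
      "500": [[0, 100], [4, 1.5], [12, 1.5], [24, 20]],
      "1000": [[0, 100], [2, 0], [14, 1.5], [24, 5.5]]
    },
    "ci": {
      "150": [[0, 100], [12, 82], [24, 90]],
      "300": [[0, 100], [12, 74], [24, 82]],
      "500": [[0, 100], [12, 70], [16, 71], [24, 78]],
      "1000": [[0, 100], [12, 65], [24, 75]]
    }
  },
  "e4031": {
    "force": {
      "5": [[0, 100], [24, 100]],
      "10": [[0, 100], [24, 100]],
      "20": [[0, 100], [24, 100]],
      "30": [[0, 100], [24, 100]]
    },
    "ci": {
      "5": [[0, 100], [12, 88], [24, 80]],
      "10": [[0, 100], [12, 82], [24, 72]],
      "20": [[0, 100], [12, 78], [24, 66.5]],
      "30": [[0, 100], [12, 74], [24, 64]]
    },
    "durationFactor": {
      "30": [[0, 1.0], [12, 1.22], [14, 1.13], [24, 1.12]]
    },
    "jitterFactor": {
      "30": [[0, 1.0], [12, 5.0], [24, 2.0]]
    }
  }
}
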