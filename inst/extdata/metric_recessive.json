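{
  "model": "recessive",
  "q_coef": [0.116065310209144, 0.0960000935913062, -0.189694158863122, 0.0111981103221744],
  "tail_lo": 0.175,
  "tail_lo_val": 0.0183523664138643,
  "tail_hi": 0.825,
  "tail_hi_val": 0.0104589169004705,
  "scale": 3311.86780408917,
  "bins": {
    "mid": [0.025, 0.075, 0.125, 0.175, 0.225, 0.275, 0.325, 0.375, 0.425, 0.475, 0.525, 0.575, 0.625, 0.675, 0.725, 0.775, 0.825, 0.875, 0.925, 0.975],
    "n": [382278, 101138, 66825, 51374, 41844, 35490, 31704, 28134, 25657, 24066, 21806, 21193, 19932, 19502, 18774, 18639, 18301, 19095, 20216, 24927],
    "prob": [2.8774870643877e-05, 0.00236310783286203, 0.00963711185933408, 0.0175185891696189, 0.0227272727272727, 0.026007326007326, 0.0283560434014635, 0.0303547309305467, 0.0293097400319601, 0.0287958115183246, 0.0293955791983858, 0.0268956730996084, 0.0247842665061208, 0.0209722079786689, 0.019335250878875, 0.0141638499919524, 0.00978088629036665, 0.00466090599633412, 0.00138504155124654, 0.0002407028523288],
    "in_core": [false, false, false, true, true, true, true, true, true, true, true, true, true, true, true, true, true, false, false, false]
  },
  "config": {
    "n_replicates": 1000000,
    "n_cases": 1000,
    "n_controls": 1000,
    "penetrances": [0.01, 0.01, 0.0225],
    "top_fraction": 0.01,
    "bin_width": 0.05,
    "poly_degree": 5,
    "n_tail_bins_excluded": 3,
    "seed": 1
  }
}
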