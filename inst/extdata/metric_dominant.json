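{
  "model": "dominant",
  "q_coef": [0.114401989219689, 0.195627196908048, -0.516321734721288, 0.249538509335013],
  "tail_lo": 0.175,
  "tail_lo_val": 0.0193696049664268,
  "tail_hi": 0.825,
  "tail_hi_val": 0.00931113616196743,
  "scale": 3306.13978813151,
  "bins": {
    "mid": [0.025, 0.075, 0.125, 0.175, 0.225, 0.275, 0.325, 0.375, 0.425, 0.475, 0.525, 0.575, 0.625, 0.675, 0.725, 0.775, 0.825, 0.875, 0.925, 0.975],
    "n": [382448, 104075, 69392, 51987, 42784, 36314, 31737, 28256, 25564, 23857, 21892, 21022, 19538, 18693, 18217, 18054, 17820, 18121, 19120, 22849],
    "prob": [0.000172572480441786, 0.00280566898871006, 0.00868976250864653, 0.0176582607190259, 0.0241679132385939, 0.0287492427163078, 0.0297129533352239, 0.0281710079275198, 0.0313722422156157, 0.0279582512470135, 0.0260369084597113, 0.0264484825420988, 0.0237485924864367, 0.0188840742523939, 0.016083877696657, 0.0130165060374432, 0.0085297418630752, 0.00491142872909884, 0.00188284518828452, 0.000218827957459845],
    "in_core": [false, false, false, true, true, true, true, true, true, true, true, true, true, true, true, true, true, false, false, false]
  },
  "config": {
    "n_replicates": 1000000,
    "n_cases": 1000,
    "n_controls": 1000,
    "penetrances": [0.01, 0.0225, 0.0225],
    "top_fraction": 0.01,
    "bin_width": 0.05,
    "poly_degree": 5,
    "n_tail_bins_excluded": 3,
    "seed": 1
  }
}
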