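{
  "model": "multiplicative",
  "q_coef": [0.196580885178297, -0.210954925288407, -0.0307100358891058, 0.0551873158761243],
  "tail_lo": 0.175,
  "tail_lo_val": 0.0229583750441352,
  "tail_hi": 0.825,
  "tail_hi_val": 0.00471089760553812,
  "scale": 3597.60016954219,
  "bins": {
    "mid": [0.025, 0.075, 0.125, 0.175, 0.225, 0.275, 0.325, 0.375, 0.425, 0.475, 0.525, 0.575, 0.625, 0.675, 0.725, 0.775, 0.825, 0.875, 0.925, 0.975],
    "n": [383548, 102136, 67109, 51505, 42151, 35754, 31970, 28250, 25650, 24085, 22143, 20747, 19764, 19396, 18613, 18250, 18208, 18687, 19894, 23558],
    "prob": [0.000172077549615693, 0.00699067909454061, 0.0164657497504061, 0.0229492282302689, 0.0256933406087637, 0.0271578005258153, 0.0280262746324679, 0.0287787610619469, 0.0238206627680312, 0.0240398588332987, 0.0219482454951904, 0.0174001060394274, 0.0162922485326857, 0.0126830274283357, 0.00945575672916779, 0.00717808219178082, 0.00455843585237258, 0.00240809118638626, 0.00170905800743943, 0.000466932676797691],
    "in_core": [false, false, false, true, true, true, true, true, true, true, true, true, true, true, true, true, true, false, false, false]
  },
  "config": {
    "n_replicates": 1000000,
    "n_cases": 1000,
    "n_controls": 1000,
    "penetrances": [0.01, 0.015, 0.0225],
    "top_fraction": 0.01,
    "bin_width": 0.05,
    "poly_degree": 5,
    "n_tail_bins_excluded": 3,
    "seed": 1
  }
}
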