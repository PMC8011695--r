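{
  "comment": "Estimated neg-crossentropies to/from the empirical generating process and its estimated neg-selfentropy, for the published 300-tide horseshoe-crab run. sgfi/sfig are totals over the 300 tides; sgg is the nearest-neighbour estimate on the 6-dimensional count vectors and is on a different (per-vector) scale.",
  "labels": ["Poisson", "NegBin", "ZIPoiss", "ZINegBi", "HurdNBi", "PoisNB", "NBPois", "OIPoiss", "OINegBi"],
  "sgfi": [-7891.890, -5652.049, -5403.773, -5200.907, -5179.331, -5323.294, -5253.094, -7891.705, -7051.753],
  "sfig": [-7638.034, -5682.275, -5396.418, -5213.190, -5193.804, -5339.449, -5264.447, -7637.716, -6906.558],
  "sgg": -15.96137
}
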