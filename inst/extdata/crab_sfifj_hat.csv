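"","Poisson","NegBin","ZIPoiss","ZINegBi","HurdNBi","PoisNB","NBPois","OIPoiss","OINegBi"
"Poisson",-4693.860,-6788.198,-7144.127,-7261.358,-7276.347,-7240.670,-7268.412,-4694.360,-5474.936
"NegBin",-7140.595,-4801.609,-5748.393,-5402.616,-5393.795,-5141.644,-5417.371,-7142.133,-6271.978
"ZIPoiss",-7269.760,-5688.618,-4778.731,-4958.789,-4991.042,-5157.351,-4973.420,-7271.568,-6703.770
"ZINegBi",-7483.025,-5374.228,-4980.700,-4792.072,-4868.308,-5004.579,-4952.840,-7484.694,-6719.950
"HurdNBi",-7504.330,-5366.989,-5015.873,-4870.053,-4792.890,-4980.233,-4974.241,-7503.976,-6688.178
"PoisNB",-7476.723,-5131.165,-5178.562,-5008.269,-4982.275,-4794.920,-4975.992,-7477.044,-6595.687
"NBPois",-7453.540,-5389.715,-4984.999,-4949.951,-4969.751,-4970.038,-4790.289,-7455.437,-6702.133
"OIPoiss",-4694.328,-6789.643,-7145.910,-7262.925,-7275.909,-7240.883,-7270.251,-4693.826,-5474.358
"OINegBi",-5606.894,-6051.992,-6648.368,-6590.061,-6559.321,-6453.790,-6596.554,-5606.393,-4735.259
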