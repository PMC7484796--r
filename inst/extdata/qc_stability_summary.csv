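condition,conc_level,nominal_ng_ml,mean_ng_ml,sd_ng_ml
freeze_thaw,low,10,9.880,0.1378
freeze_thaw,high,200,196.888,1.757
long_term,low,10,9.775,0.268
long_term,high,200,195.806,0.967
stock_solution,low,10,10.008,0.050
stock_solution,high,200,199.975,1.032
benchtop,low,10,10.016,0.294
benchtop,high,200,200.109,0.651
autosampler,low,10,10.006,0.638
autosampler,high,200,199.899,0.519
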