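parameter,part1_ir,part1_er,part2_fasted,part2_fed
cmax_ng_ml,98.0512,84.0517,84.0328,80.0492
tmax_h,3.0295,5.1163,5.117,5.5798
auc_0_t,1169.9639,1181.2261,1181.2283,1193.6146
auc_0_inf,1253.4172,1265.1170,1265.3826,1275.1107
mrt_0_t,14.795,14.652,14.652,14.727
mrt_0_inf,17.561,17.418,17.427,17.374
cl_f,47.869,47.426,47.417,47.055
vz_f,399.010,397.022,397.463,383.293
kel,0.127,0.119,0.119,0.123
t_half,5.448,5.803,5.810,5.646
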