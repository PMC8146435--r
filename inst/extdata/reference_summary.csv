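quantity,effective_mean,effective_sd,entire_mean,entire_sd
ccr,95.55,0.7725,96.14,0.0705
auc_D0,0.998,0.0009,0.998,0.0013
auc_D1,0.993,0.0023,0.994,0.0029
auc_D2,0.996,0.0007,0.998,0.0008
auc_D3,0.995,0.0017,0.996,0.0002
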