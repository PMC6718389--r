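label,stage,effect,ci_low,ci_high,p,n_cases,n_controls,scale
Combined_discovery,discovery,1.1,1.06,1.14,4.64e-8,7888,52807,odds_ratio
MoBa_HARVEST,replication,1.05,0.89,1.24,0.39,670,5626,odds_ratio
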