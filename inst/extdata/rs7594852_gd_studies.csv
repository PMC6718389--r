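label,stage,effect,ci_low,ci_high,p,n,scale
Combined_discovery,discovery,0.034,0.024,0.043,1.88e-12,84689,linear
MoBa_HARVEST,replication,0.049,0.016,0.082,3.78e-3,7072,linear
BiB,replication,0.058,-0.028,0.144,0.18,1354,linear
FIN,replication,0.004,-0.056,0.065,0.89,865,linear
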