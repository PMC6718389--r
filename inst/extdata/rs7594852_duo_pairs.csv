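label,n,estimate,effect,ci_low,ci_high,p
MoBa_HARVEST,6362,fetal_unadj,0.041,0.001,0.076,0.020
MoBa_HARVEST,6362,fetal_adj,0.051,0.011,0.092,0.013
MoBa_HARVEST,6362,maternal_unadj,0.0065,-0.029,0.041,0.72
MoBa_HARVEST,6362,maternal_adj,-0.020,-0.060,0.021,0.34
ALSPAC,4305,fetal_unadj,0.028,-0.013,0.07,0.18
ALSPAC,4305,fetal_adj,0.021,-0.027,0.07,0.39
ALSPAC,4305,maternal_unadj,0.025,-0.017,0.067,0.24
ALSPAC,4305,maternal_adj,0.014,-0.034,0.063,0.57
DNBC,1396,fetal_unadj,-0.016,-0.09,0.059,0.68
DNBC,1396,fetal_adj,-0.009,-0.094,0.077,0.84
DNBC,1396,maternal_unadj,-0.018,-0.090,0.054,0.63
DNBC,1396,maternal_adj,-0.014,-0.097,0.069,0.75
BiB,1182,fetal_unadj,0.09,-0.002,0.18,0.055
BiB,1182,fetal_adj,0.090,-0.015,0.19,0.09
BiB,1182,maternal_unadj,0.045,-0.049,0.14,0.35
BiB,1182,maternal_adj,0.00065,-0.11,0.11,0.99
MoBa_2008,854,fetal_unadj,-0.040,-0.139,0.058,0.42
MoBa_2008,854,fetal_adj,-0.026,-0.138,0.085,0.64
MoBa_2008,854,maternal_unadj,-0.041,-0.137,0.056,0.41
MoBa_2008,854,maternal_adj,-0.029,-0.138,0.080,0.61
FIN,833,fetal_unadj,-0.012,-0.073,0.050,0.57
FIN,833,fetal_adj,0.021,-0.053,0.094,0.58
FIN,833,maternal_unadj,-0.005,-0.057,0.066,0.88
FIN,833,maternal_adj,-0.029,-0.10,0.045,0.44
EFSOCH,656,fetal_unadj,-0.037,-0.147,0.073,0.51
EFSOCH,656,fetal_adj,0.028,-0.098,0.154,0.67
EFSOCH,656,maternal_unadj,-0.114,-0.221,-0.007,0.037
EFSOCH,656,maternal_adj,-0.128,-0.251,-0.005,0.043
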