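structure,metric,plan1,plan2,plan3
PTV,coverage,99.60,99.95,99.86
PTV_H,coverage,99.10,99.90,98.40
PTV_N,coverage,99.15,99.88,99.76
PTV,CI,0.75,0.54,0.55
PTV_H,CI,0.44,0.64,0.72
PTV_N,CI,0.28,0.21,0.21
PTV,IOA,1.02,1.10,1.09
PTV_H,IOA,1.03,1.02,1.01
PTV_N,IOA,1.01,1.08,1.06
PTV,D2,64.42,77.42,79.91
PTV_H,D2,64.38,77.58,80.40
PTV_N,D2,64.39,76.50,77.07
PTV,D98,61.17,66.27,65.31
PTV_H,D98,61.74,73.67,72.37
PTV_N,D98,60.55,64.89,63.67
PTV,Dmean,63.29,74.92,74.05
PTV_H,Dmean,63.43,75.86,75.62
PTV_N,Dmean,63.05,72.07,70.49
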