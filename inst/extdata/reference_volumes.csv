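structure,mean_cc,sd_cc,ratio_pct
GTV,34.5,21.7,NA
GTV_H,17.0,11.9,49.3
PTV,72.0,34.7,NA
PTV_H,41.5,22.0,57.6
PTV_N,30.5,18.6,42.4
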