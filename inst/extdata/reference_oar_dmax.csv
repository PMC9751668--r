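oar,plan1,plan2,plan3
Eye-L,8.74,8.97,8.98
Eye-R,8.92,9.39,9.42
OpticNerve-L,8.36,8.62,8.67
OpticNerve-R,7.36,7.66,7.75
Lens-L,2.31,2.37,2.40
Lens-R,2.07,2.14,2.15
Brainstem,18.68,19.09,19.14
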