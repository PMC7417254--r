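model,k,AIC,AICc
50% Core,1,14,14.22
Core + Total,2,16.73,17.44
90% Total,1,17.9,18.12
Biomass,1,30,30.22
SL Wet,1,30,30.22
SL Dry,1,30.9,31.12
BTb,1,33.36,33.59
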