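response,region,model,k,AIC,AICc
birth,south,prey + rain,2,19.32,20.03
birth,north,prey + rain,2,21.05,21.75
conception,south,prey + rain,2,18.64,19.35
conception,north,prey + rain,2,16.41,17.12
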