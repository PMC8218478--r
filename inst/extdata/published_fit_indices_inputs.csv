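K,Npar,L2,df,N
1,18,383.92,205,223
2,54,268.71,169,223
3,90,154.03,133,223
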