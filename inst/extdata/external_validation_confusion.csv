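observed,no,non-violent,violent
no,51,1,1
non-violent,4,13,0
violent,0,0,6
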