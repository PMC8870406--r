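actual,cancer,normal,stroma
cancer,95,1,20
normal,0,248,3
stroma,5,4,0
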