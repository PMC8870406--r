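actual,cancer,normal
cancer,14,0
normal,1,17
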