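region,left,right
upper,8.1,9.66
middle,21.79,25.97
lower,16.82,17.66
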