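"code","label"
1,"glargine (once)"
2,"NPH (twice)"
3,"detemir (once)"
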