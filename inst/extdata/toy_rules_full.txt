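# full-activity variant of the toy regulatory network
R7r = NOT(fR9)
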