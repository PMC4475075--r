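# 1-activity variant: consulted only when R9 carries flux
R7r = NOT(1R9)
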