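s1	pop1
s2	pop1
s3	pop1
s4	pop1
s5	pop2
s6	pop2
s7	pop2
s8	pop2
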