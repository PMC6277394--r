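sample	sex	group
s1	F	pop
s2	M	pop
s3	F	pop
s4	U	pop
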