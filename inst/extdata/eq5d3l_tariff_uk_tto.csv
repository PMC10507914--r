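term,value
constant,0.081
mobility2,0.069
mobility3,0.314
selfcare2,0.104
selfcare3,0.214
activity2,0.036
activity3,0.094
pain2,0.123
pain3,0.386
anxiety2,0.071
anxiety3,0.236
n3,0.269
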