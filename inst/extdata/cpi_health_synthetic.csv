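year,index
2014,99.6
2015,100.0
2016,100.4
2017,100.9
2018,101.5
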