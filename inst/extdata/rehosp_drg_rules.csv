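reason,drg_code
respiratory,04M051
respiratory_severe,04M052
cardiac,05M091
infection,18M071
pleural,04M161
other,23M061
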