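seq,element_id,raw_value
1,0,42
2,1,90
3,1,98
4,2,93
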