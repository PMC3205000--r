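seq,element_id,raw_value
1,0,42
2,4,80
3,7,50
4,7,46
5,4,102
6,7,44
7,7,42
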