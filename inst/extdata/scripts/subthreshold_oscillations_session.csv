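seq,element_id,raw_value
1,0,42
2,1,61
3,6,56
4,9,70
5,9,74
6,5,60
7,5,50
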