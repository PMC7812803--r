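sort	unmutated	total
1	6	45
2	3	56
3	5	61
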