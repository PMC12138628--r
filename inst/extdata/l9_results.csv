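run,conversion_mean,conversion_sd
1,89.1,0.1
2,86.0,0.1
3,68.9,0.1
4,81.0,0.6
5,73.6,0.3
6,78.6,0.6
7,53.3,0.2
8,82.0,0.5
9,63.6,0.6
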