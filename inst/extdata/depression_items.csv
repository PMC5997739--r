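item,1,2,3,4,5,6,7,8,9,10,r_crit
1,1,0.32,0.27,0.41,0.27,0.15,0.22,0.36,0.19,0.42,0.22
2,0.32,1,0.5,0.31,0.32,0.42,0.38,0.42,0.19,0.46,0.21
3,0.27,0.5,1,0.31,0.38,0.36,0.27,0.44,0.18,0.44,0.23
4,0.41,0.31,0.31,1,0.34,0.15,0.29,0.42,0.1,0.57,0.28
5,0.27,0.32,0.38,0.34,1,0.3,0.31,0.49,0.2,0.41,0.2
6,0.15,0.42,0.36,0.15,0.3,1,0.28,0.28,0.1,0.27,0.22
7,0.22,0.38,0.27,0.29,0.31,0.28,1,0.44,0.14,0.35,0.26
8,0.36,0.42,0.44,0.42,0.49,0.28,0.44,1,0.33,0.55,0.25
9,0.19,0.19,0.18,0.1,0.2,0.1,0.14,0.33,1,0.26,0.13
10,0.42,0.46,0.44,0.57,0.41,0.27,0.35,0.55,0.26,1,0.35
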