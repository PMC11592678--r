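# 13-node sparse toy network; edges (1,2),(1,7),(2,7) form its single triangle
1 7
2 7
1 4
1 5
1 6
1 13
1 2
2 8
2 9
2 11
4 3
13 3
9 10
11 12
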