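>forkhead_synthetic synthetic forkhead-family-like example matrix (not a JASPAR snapshot)
A [ 30  5 90 92 95  2 80 40 ]
C [ 20  8  3  2  2 90  5 15 ]
G [ 35  5  4  3  1  3  5 25 ]
T [ 15 82  3  3  2  5 10 20 ]
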