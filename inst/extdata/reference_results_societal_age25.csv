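strategy,ly,qaly,cost
Int2,7.73,6.91,687062
B,8.88,7.42,690438
A,7.35,6.47,697523
Int1,8.73,7.82,698459
C,7.00,6.15,707752
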