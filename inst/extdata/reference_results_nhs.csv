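strategy,ly,qaly,cost
C,6.37,5.60,69704
A,6.61,5.82,71576
Int2,6.65,5.93,91790
B,7.63,6.44,107703
Int1,7.45,6.67,119088
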