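threshold,stratum,n,up,down
0.10,event,1697.81,65.36,100.58
0.10,nonevent,15928.64,785.56,1156.07
0.20,event,1707.7,146.1,124.3
0.20,nonevent,15928.64,783.85,927.36
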