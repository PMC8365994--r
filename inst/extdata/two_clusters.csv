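step,id,x,y,theta,omega
0,1,0,0,0,0
0,2,0.1,0,0,0
0,3,5,5,1.5708,0
0,4,5.1,5,1.5708,0
1,1,0.2,0,0,0
1,2,0.3,0,0,0
1,3,5,5.2,1.5708,0
1,4,5.1,5.2,1.5708,0
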