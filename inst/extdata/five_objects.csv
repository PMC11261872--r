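id,a,b,c,d
c1,8,45,80,1
c2,20,3,100,0
c3,40,9,18,1
c4,13,17,30,0
c5,50,9,15,1
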