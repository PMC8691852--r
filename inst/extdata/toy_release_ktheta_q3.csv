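CaseID,Sex,Age,ADR,Group
13,F,[39-45],"h,k",1
26,F,[39-45],"x,u",1
28,F,[39-45],"d,i",1
23,F,[39-45],z,1
15,*,[38-40],x,2
27,*,[38-40],"a,c",2
24,*,[38-40],d,2
25,*,[38-40],"e,q",2
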