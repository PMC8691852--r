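CaseID,Sex,Age,ADR,Group
13,F,[39-46],"h,k",1
26,F,[39-46],"x,u",1
28,F,[39-46],"d,i",1
23,F,[39-46],z,1
15,*,[38-46],x,2
27,*,[38-46],"a,c",2
24,*,[38-46],d,2
25,*,[38-46],"e,q",2
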