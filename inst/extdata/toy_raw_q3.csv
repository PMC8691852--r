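CaseID,Sex,Age,ADR
13,F,40,"h,k"
26,F,45,"x,u"
28,F,45,"d,i"
23,F,40,z
15,F,39,x
27,M,38,"a,c"
24,M,38,d
25,M,38,"e,q"
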