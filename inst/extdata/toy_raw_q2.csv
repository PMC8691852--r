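CaseID,Sex,Age,ADR
1,M,50,"c,b"
11,M,50,a
12,M,53,y
14,M,48,h
16,M,48,"q,d,e,p,x"
15,F,40,x
18,F,39,q
17,M,46,"y,b,c,f,g,i"
19,F,43,o
3,M,46,d
20,F,40,"x,i"
21,F,46,"j,z,v,u,k,n"
22,M,46,"q,l"
13,F,39,"h,o"
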