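CaseID,Sex,Age,ADR,Group
1,M,[48-53],"c,b",1
11,M,[48-53],a,1
12,M,[48-53],y,1
14,M,[48-53],h,1
16,M,[48-53],"q,d,e,p,x",1
15,*,[40-46],x,2
18,*,[40-46],q,2
17,*,[40-46],"y,b,c,f,g,i",2
19,*,[40-46],o,2
3,*,[39-46],d,3
20,*,[39-46],"x,i",3
21,*,[39-46],"j,z,v,u,k,n",3
22,*,[39-46],"q,l",3
13,*,[39-46],"h,o",3
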