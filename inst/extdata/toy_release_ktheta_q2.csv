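CaseID,Sex,Age,ADR,Group
1,M,[48-53],"c,b",1
11,M,[48-53],a,1
12,M,[48-53],y,1
14,M,[48-53],h,1
13,F,[39-40],"h,o",2
15,F,[39-40],x,2
18,F,[39-40],q,2
16,*,[46-48],"q,d,e,p,x",3
17,*,[46-48],"y,b,c,f,g,i",3
21,*,[46-48],"j,z,v,u,k,n",3
3,*,[40-46],d,4
20,*,[40-46],"x,i",4
19,*,[40-46],o,4
22,*,[40-46],"q,l",4
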