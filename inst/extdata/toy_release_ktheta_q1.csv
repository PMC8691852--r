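CaseID,Sex,Age,ADR,Group
1,M,[46-50],"c,b",1
7,M,[46-50],a,1
3,M,[46-50],d,1
5,M,[46-50],"e,g",1
2,F,[21-25],"c,a",2
4,F,[21-25],"b,d",2
6,F,[21-25],y,2
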