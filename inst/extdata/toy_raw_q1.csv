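CaseID,Sex,Age,ADR
1,M,50,"c,b"
7,M,48,a
3,M,46,d
5,M,46,"e,g"
2,F,21,"c,a"
4,F,23,"b,d"
6,F,25,y
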