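ID,TIME,EVID,AMT,CMT,RATE,II,ADDL,DV,WT,HT,AGE,SEX,SCR
1,0,1,200,1,0,12,0,.,65.1,165.1,50.2,0,1
1,4,0,.,1,0,.,.,3.549,65.1,165.1,50.2,0,1
1,12,0,.,1,0,.,.,4.293,65.1,165.1,50.2,0,1
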