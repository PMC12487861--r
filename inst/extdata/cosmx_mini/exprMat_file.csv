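fov,cell_ID,IL36G,CD4,FOXP3,IL2RA,IL17A,RORC,IL17F,IL26,CD8A,NKG7,KLRD1,CD3E,CTLA4,ACTB,NegPrb1,SystemControl1
1,1,4,1,6,4,0,2,1,4,2,3,3,3,1,3,0,3
1,2,0,1,4,2,1,2,0,5,2,5,4,2,5,2,1,1
1,3,1,3,0,3,3,1,1,2,2,5,3,2,3,1,1,3
1,4,3,1,0,1,1,2,1,3,0,1,2,0,2,1,1,2
1,5,3,2,1,0,0,1,2,0,1,4,4,3,1,2,3,2
2,1,2,1,1,1,4,5,3,3,2,0,2,3,3,2,2,2
2,2,0,1,2,3,1,2,2,2,3,1,4,5,1,3,4,2
2,3,2,4,3,2,3,0,3,2,1,0,2,3,3,3,1,4
2,4,1,1,3,1,3,1,3,3,1,0,1,3,4,2,2,1
2,5,2,1,2,1,0,1,3,2,2,2,2,1,3,2,3,3
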