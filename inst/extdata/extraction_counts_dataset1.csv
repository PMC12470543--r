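Sample,Single Cells,Extracted Cells,Overlapping,Small Cells,Touching Edge,Other
IDA,733,132,20,168,25,0
TT,1124,65,17,94,50,0
HbH,1551,379,427,328,70,0
HbE/b-thal,5009,732,476,590,104,0
HbE/b-thal Sx,930,445,211,853,63,0
Homo HbE,2803,148,93,204,68,0
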