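Sample,Single Cells,Extracted Cells,Overlapping,Small Cells,Touching Edge,Other
IDA,785,164,30,853,35,0
TT,1874,239,381,298,59,0
HbH,1167,270,362,232,68,0
HbE/b-thal,2443,640,496,415,71,0
HbE/b-thal Sx,381,280,174,723,49,0
Homo HbE,3013,240,271,291,66,0
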