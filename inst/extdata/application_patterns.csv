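# frame: y|n
entity,attribute,subset,magnitude,phase_tan
p1,a1,y,0.9901,0.0101
p1,a1,n,0,0
p1,a1,y|n,0.0141,-1.0000
p1,a2,y,0.8062,0.1250
p1,a2,n,0,0
p1,a2,y|n,0.2236,-0.5000
p1,a3,y,0.7071,0.1429
p1,a3,n,0.1118,-0.5000
p1,a3,y|n,0.2062,-0.2500
p2,a1,y,0.9055,0.1111
p2,a1,n,0.1414,-1.0000
p2,a1,y|n,0,0
p2,a2,y,0.9901,0.0101
p2,a2,n,0,0
p2,a2,y|n,0.0141,-1.0000
p2,a3,y,0.9055,0.1111
p2,a3,n,0,0
p2,a3,y|n,0.1414,-1.0000
p3,a1,y,0.6083,0.1667
p3,a1,n,0.2062,-0.2500
p3,a1,y|n,0.2062,-0.2500
p3,a2,y,0.8062,0.1250
p3,a2,n,0,0
p3,a2,y|n,0.2236,-0.5000
p3,a3,y,0.9901,0.0101
p3,a3,n,0,0
p3,a3,y|n,0.0141,-1.0000
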