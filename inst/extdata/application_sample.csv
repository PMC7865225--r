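# frame: y|n
entity,attribute,subset,magnitude,phase_tan
s1,a1,y,0.5099,0.2000
s1,a1,n,0.3041,-0.1667
s1,a1,y|n,0.2062,-0.2500
s1,a2,y,0.6083,0.1667
s1,a2,n,0.2062,-0.2500
s1,a2,y|n,0.2062,-0.2500
s1,a3,y,0.8062,0.1250
s1,a3,n,0.1118,-0.5000
s1,a3,y|n,0.1118,-0.5000
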