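"fluorophore_tag","replicate_id","deltaF_over_G"
"TMR-C1",1,34336.9225191049
"TMR-C1",2,28491.8135387644
"TMR-C1",3,31293.5746770683
"TMR-C1",4,32108.091953713
"TMR-C1",5,31417.8050109149
"TMR-C2",1,2358.28574746703
"TMR-C2",2,2743.86495993065
"TMR-C2",3,2361.01863738876
"TMR-C2",4,2864.68910969752
"TMR-C2",5,2368.63297368403
"TMR-C3",1,-17718.4919432011
"TMR-C3",2,-19257.2611678199
"TMR-C3",3,-13496.5202568365
"TMR-C3",4,-15236.372305182
"TMR-C3",5,-15464.3681665051
"TMR-C4",1,-14599.3963406981
"TMR-C4",2,-13336.2827991342
"TMR-C4",3,-10080.0881767228
"TMR-C4",4,-10376.5639486591
"TMR-C4",5,-15538.5099751809
"TMR-C5",1,-10007.432402407
"TMR-C5",2,-8484.98233367563
"TMR-C5",3,-10146.5186934454
"TMR-C5",4,-11578.037201666
"TMR-C5",5,-12280.6051989811
"TMR-C6",1,-9474.06630141579
"TMR-C6",2,-9645.53822897835
"TMR-C6",3,-8154.66715328249
"TMR-C6",4,-10355.7485964376
"TMR-C6",5,-9266.63076239488
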