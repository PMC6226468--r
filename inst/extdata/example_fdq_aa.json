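{"TMR-C1":{"tag":"TMR-C1","anchor_pair":"aa","alpha":[0.040000000000000001],"delta":[2.5],"A":[0.70185591689668003,0.210556775069004],"mu":[8,4.4000000000000004],"sigma":[2.7999999999999998,2.2399999999999998],"ksv_scale":1},"TMR-C2":{"tag":"TMR-C2","anchor_pair":"aa","alpha":[0.040000000000000001],"delta":[2.5],"A":[0.77705476513561023,0.23311642954068301],"mu":[11,6.0500000000000007],"sigma":[3.1000000000000001,2.4800000000000004],"ksv_scale":1},"TMR-C3":{"tag":"TMR-C3","anchor_pair":"aa","alpha":[0.040000000000000001],"delta":[2.5],"A":[0.8522536133745402,0.25567608401236203],"mu":[14,7.7000000000000011],"sigma":[3.3999999999999999,2.7200000000000002],"ksv_scale":1},"TMR-C4":{"tag":"TMR-C4","anchor_pair":"aa","alpha":[0.040000000000000001],"delta":[2.5],"A":[0.92745246161347017,0.27823573848404104],"mu":[17,9.3500000000000014],"sigma":[3.7000000000000002,2.9600000000000004],"ksv_scale":1},"TMR-C5":{"tag":"TMR-C5","anchor_pair":"aa","alpha":[0.040000000000000001],"delta":[2.5],"A":[1.0026513098524001,0.30079539295572],"mu":[20,11],"sigma":[4,3.2000000000000002],"ksv_scale":1},"TMR-C6":{"tag":"TMR-C6","anchor_pair":"aa","alpha":[0.040000000000000001],"delta":[2.5],"A":[1.07785015809133,0.32335504742739907],"mu":[23,12.65],"sigma":[4.2999999999999998,3.4399999999999999],"ksv_scale":1}}
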