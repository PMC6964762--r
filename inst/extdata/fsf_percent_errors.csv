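field_cm,tps_pct,film_pct,lynx_pct
2.0,6.0,3.6,0.8
3.2,2.1,0.1,-1.5
4.0,1.0,0.1,-1.1
6.0,1.3,0.3,-0.2
10.0,0.0,0.0,0.0
14.0,-0.3,-0.3,-0.6
20.0,-0.2,-0.4,-0.5
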