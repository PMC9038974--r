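id,day,sorbent_myo1,mass_myo1_g,sorbent_myo2,mass_myo2_g,sorbent_myo3,mass_myo3_g,arterial_flow_L_min,flow_myo1_mL_min,flow_myo2_mL_min,flow_myo3_mL_min,perfusion_rate_pct,filters
D1#1,1,AC+Z,30,AC+Z,15,none,0,4.5,100,100,100,6.7,n
D1#2,1,AC+Z,30,AC+Z,15,none,0,4.5,100,100,100,6.7,n
D2#3,2,AC+Z,30,AC+Z,15,none,0,4.0,100,100,100,7.5,y
D2#4,2,AC+Z,30,AC+Z,15,none,0,4.0,100,100,100,7.5,y
D2#5,2,AC+Z,30,AC+Z,15,none,0,4.0,50,100,100,6.3,y
D2#6,2,AC+Z,30,AC+Z,15,none,0,4.0,50,125,125,7.5,y
D3#7,3,Z,7,Z,7,Z,7,4.0,80,80,80,6.0,y
D3#8,3,Z,7,Z,7,Z,7,4.0,80,40,80,5.0,y
D3#9,3,Z,7,Z,7,Z,7,4.0,80,0,80,4.0,y
D3#10,3,Z,7,Z,7,Z,7,4.0,80,40,80,5.0,y
D4#11,4,AC+Z,20,AC+Z,20,AC+Z,20,4.0,80,80,80,6.0,y
D4#12,4,AC+Z,20,AC+Z,20,AC+Z,20,4.0,80,80,80,6.0,y
D4#13,4,AC+Z,20,AC+Z,20,AC+Z,20,4.0,40,40,40,3.0,y
D4#14,4,AC+Z,20,AC+Z,20,AC+Z,20,4.0,80,0,80,4.0,y
D5#15,5,AC,7,AC,7,AC,7,4.0,80,40,80,5.0,y
D5#16,5,AC,7,AC,7,AC,7,4.0,40,80,40,4.0,y
D5#17,5,AC,7,AC,7,AC,7,4.0,40,40,40,3.0,y
D5#18,5,AC,7,AC,7,AC,7,4.0,80,80,80,6.0,y
D6#19,6,AC,7,AC,7,AC,7,4.0,40,40,40,3.0,y
D6#20,6,AC,7,AC,7,AC,7,4.0,80,80,80,6.0,y
D6#21,6,AC,7,AC,7,AC,7,4.0,80,80,80,6.0,y
D6#22,6,AC,7,AC,7,AC,7,4.0,40,80,80,5.0,y
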