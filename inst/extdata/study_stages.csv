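process,stage_id,ph,temperature_c,nh4_n_i,nh4_n_e,no2_n_e,no3_n_i,no3_n_e,do_mg_l,s2_s_i,s2_s_e,so4_s_e,n2o_prod,s0_prod,no2_prod,stable
nitrification,1,7.5,23,500,124,170,,170,0.5,,,,10.6,,,TRUE
nitrification,2,7.5,23,500,124,170,,170,1.0,,,,18.7,,,TRUE
nitrification,3,7.5,23,500,124,170,,170,2.0,,,,13.8,,,TRUE
nitrification,4,7.5,23,500,124,170,,170,5.0,,,,12.4,,,TRUE
nitrification,5,7.5,23,500,122,90,,236,0.5,,,,2.3,,,TRUE
nitrification,6,7.5,23,500,122,90,,236,1.0,,,,9.8,,,TRUE
nitrification,7,7.5,23,500,122,90,,236,2.0,,,,7.5,,,TRUE
nitrification,8,7.5,23,500,122,90,,236,5.0,,,,6.6,,,TRUE
nitrification,9,7.5,23,500,9,3,,451,0.5,,,,1.2,,,TRUE
nitrification,10,7.5,23,500,9,3,,451,1.0,,,,4.0,,,TRUE
nitrification,11,7.5,23,500,9,3,,451,2.0,,,,1.8,,,TRUE
nitrification,12,7.5,23,500,9,3,,451,5.0,,,,0.0,,,TRUE
denitrification,1,7.8,30,,,,450,,,200,,,,,,FALSE
denitrification,2,8.0,30,,,110,450,294,,250,0.9,205,,6.5,18.3,TRUE
denitrification,3,8.6,30,,,12,450,291,,300,0.7,128,,30.8,2.1,TRUE
denitrification,4,9.3,30,,,22,450,362,,200,1.0,24,,32.3,3.6,TRUE
denitrification,5,7.5,30,,,,450,,,100,,,,,,FALSE
denitrification,6,8.2,30,,,94,450,306,,150,0.9,266,,-13.0,15.7,TRUE
denitrification,7,8.4,30,,,13,450,309,,300,1.0,160,,24.0,2.1,TRUE
denitrification,8,7.7,30,,,77,450,239,,350,0.9,375,,-3.2,12.9,TRUE
denitrification,9,7.7,30,,,79,450,154,,450,0.9,474,,-3.3,13.2,TRUE
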