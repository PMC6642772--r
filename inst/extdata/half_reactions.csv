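id,process,oxidized,reduced,label,e0_v,m_num,m_den
n2o_nh4,nitrification,N2O,NH4+,1/8 N2O + 5/4 H+ + e- -> 1/8 H2O + 1/4 NH4+,2.04,5,4
o2_h2o,nitrification,O2,H2O,1/4 O2 + H+ + e- -> 1/2 H2O,1.23,1,1
no2_nh4,nitrification,NO2-,NH4+,1/6 NO2- + 4/3 H+ + e- -> 1/6 NH4+ + 1/3 H2O,0.89,4,3
no3_n2,denitrification,NO3-,N2,1/5 NO3- + 6/5 H+ + e- -> 1/10 N2 + 3/5 H2O,1.25,6,5
no2_n2,denitrification,NO2-,N2,1/3 NO2- + 4/3 H+ + e- -> 1/6 N2 + 2/3 H2O,0.42,4,3
so4_hs,denitrification,SO4-2,HS-,1/8 SO4-2 + 9/8 H+ + e- -> 1/8 HS- + 1/2 H2O,0.25,9,8
s_hs,denitrification,S0,HS-,1/2 S0 + 1/2 H+ + e- -> 1/2 HS-,-0.11,1,2
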