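param,AP_av Chara APW,AP_av Nitellopsis APW,Cell 1 APW,Sorbitol 90 mM 15 min,50 mM NaCl just on,50 mM NaCl 30 min,50 mM NaCl 60 min,Cell 2 50 mM NaCl overnight,Cell 3 50 mM NaCl overnight
nu_r,0.185,,,,,,,,
gamma0,0.1,,,,,,,,
gamma1,20.5,,,,,,,,
p1_prime,8.5,9.74,9.48,9.45,6.69,6.7,4.74,5.75,9.0
p2_prime,0.035,0.0197,0.014,0.0171,0.0085,0.009,0.004,0.013,0.33
C0,1.56,,,,,,,,
k1,12.0,,,,,,,,
k_m1,8.0,,8.0,8.0,8.0,8.0,7.8,7.8,7.8
k2_prime,15.0,14.2,14.2,14.25,14.25,14.27,14.25,14.25,14.25
k_m2,1.65,1.595,1.595,1.6,1.604,1.6025,1.4,1.6,1.6
k3_prime,1.8,1.51,1.56,1.51,1.52,1.52,1.51,1.51,1.51
k_m3,0.04,0.312,0.31,0.318,0.1955,0.1956,0.25,0.28,0.25
I0,2.5,2.1,2.1,2.0,2.0,2.0,0.9,1.8,0.15
k_a,2,4.6,4.3,4.6,4.6,4.6,4.3,4.3,4.6
k_i,2,,,,,,,,
dCa,0.0355,0.009,0.011,0.008,0.02,0.009,0.009,0.008,0.004
dCa_on,0.04,0.07,0.09,0.15,0.14,0.1,0.16,0.09,0.75
dCa_off,0.16,0.16,0.18,0.2,0.17,0.17,0.19,0.18,0.765
hill_n,2,1,,,,,,,
rest_before,NA,-234,-232,-248,-240,-228,-190,-121,-68
rest_after,NA,-239,-210,-218,-202,-192,-133,-121,-69
kappa_oi,140,80,80,140,400,350,70,13,no_pump
kio0,7000,6500,6500,6500,7500,7500,6000,6000,no_pump
koi0,0.1,,,,,,,,
kappa_io,0.1,,,,,,,,
G_bkg,0.5,,0.5,0.5,1.0,1.0,1.0,1.0,1.0
V50_plus,100,,,,,,,,
z_g,1.0,,,,,,,,
NK_PK,6.5e-7,,,,,,,,
K_cyt,100,80,80,80,75,60,55,50,50
K_out,0.1,,,,,,,,
Cl_cyt,10,60,60,60,60,60,60,60,60
Cl_out,1.3,,1.3,1.3,50,50,50,50,50
Ca_cyt,0.02,,,,,,,,
Ca_out,0.1,,,,,,,,
G_Cl_max,10,4.0,5.0,7.2,80,84,20-4.1,5.0,20
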