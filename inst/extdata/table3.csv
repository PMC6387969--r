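param,AP_av Chara APW,AP_av Nitellopsis APW,Cell 5 APW,Sorbitol 180 mM 15 min,100 mM NaCl 15 min,100 mM NaCl 30 min,100 mM NaCl 60 min
nu_r,0.185,,,,,,
gamma0,0.1,,,,,,
gamma1,20.5,,,,,,
p1_prime,8.5,9.74,9.1,10.8,9.05,7.7,8.6
p2_prime,0.035,0.0197,0.016,0.045,0.012,0.011,0.053
C0,1.56,,,,,,
k1,12.0,,,,,,
k_m1,8.0,,8.1,8.1,8.1,8.1,8.1
k2_prime,15.0,14.2,14.0,14.0,14.0,14.0,14.0
k_m2,1.65,1.595,1.59,1.64,1.64,3.04,3.04
k3_prime,1.8,1.51,1.51,1.2,1.2,1.2,1.2
k_m3,0.04,0.312,0.374,0.36,0.36,0.62,0.62
I0,2.5,2.1,1.1,1.1,1.1,0.9,0.9
k_a,2,4.6,5.5,5.5,5.5,5.5,5.5
k_i,2,,,,,,
dCa,0.0355,0.009,0.007,0.008,0.0089,0.009,0.01
dCa_on,0.04,0.07,0.01,0.01,0.01,0.02,0.1
dCa_off,0.16,0.16,0.14,0.14,0.095,0.096,0.18
hill_n,2,1,,,,,
rest_before,NA,-234,-253,-231,-167,-241,-203
rest_after,NA,-239,-244,-208,-141,-235,-188
kappa_oi,140,80,175,85,40,950,100
kio0,7000,6500,7500,6500,6500,9500,6500
koi0,0.1,,,,,,
kappa_io,0.1,,,,,,
G_bkg,0.5,,0.5,0.5,1.0,1.0,1.0
V50_plus,100,,,,,,
z_g,1.0,,,,,,
NK_PK,6.5e-7,,,,,,
K_cyt,100,80,80,80,75,70,60
K_out,0.1,,,,,,
Cl_cyt,10,60,60,60,60,60,60
Cl_out,1.3,,1.3,1.3,100,100,100
Ca_cyt,0.02,,,,,,
Ca_out,0.1,,,,,,
G_Cl_max,10,4.0,6.3,3.4,13.5,80.0,15.0
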