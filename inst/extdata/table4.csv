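param,AP_av Chara APW,AP_av Nitellopsis APW,Cell 6 APW,100 mM NaCl just on,100 mM NaCl 15 min,100 mM NaCl 30 min,100 mM NaCl 60 min,100 mM NaCl 90 min
nu_r,0.185,,,,,,,
gamma0,0.1,,,,,,,
gamma1,20.5,,,,,,,
p1_prime,8.5,9.74,11.5,14.8,7.8,7.75,1.936,0.78
p2_prime,0.035,0.0197,0.0275,0.014,0.029,0.032,0.009,0.009
C0,1.56,,,,,,,
k1,12.0,,,,,,,
k_m1,8.0,,8.1,8.1,8.1,8.1,8.1,8.1
k2_prime,15.0,14.2,14.0,14.0,14.0,14.0,14.0,14.0
k_m2,1.65,1.595,1.59,1.64,3.04,3.04,3.04,3.04
k3_prime,1.8,1.51,1.51,1.5,1.2,1.2,1.2,1.2
k_m3,0.04,0.312,0.15,0.8,0.62,0.62,0.065,0.03
I0,2.5,2.1,2.1,2.1,0.7,0.81,0.86,0.86
k_a,2,4.6,5.5,5.5,5.5,5.5,5.5,5.5
k_i,2,,,,,,,
dCa,0.0355,0.009,0.016,0.03,0.0086,0.0047,0.006,0.009
dCa_on,0.04,0.07,0.04,0.15,0.02,0.02,0.1,0.15
dCa_off,0.16,0.16,0.15,0.21,0.0895,0.15,0.14,0.25
hill_n,2,1,,,,,,
rest_before,NA,-234,-120,-120,-89,-84,-103,-105
rest_after,NA,-239,-115,-89,-84,-84,-105,-101
kappa_oi,140,80,5,12,no_pump,no_pump,no_pump,no_pump
kio0,7000,6500,6000,6500,no_pump,no_pump,no_pump,no_pump
koi0,0.1,,,,,,,
kappa_io,0.1,,,,,,,
G_bkg,0.5,,0.5,1.0,1.0,1.0,1.0,1.0
V50_plus,100,,,,,,,
z_g,1.0,,,,,,,
NK_PK,6.5e-7,,,,,,,
K_cyt,100,80,80,80,50,40,35,35
K_out,0.1,,,,,,,
Cl_cyt,10,60,60,60,60,60,60,60
Cl_out,1.3,,1.3,100,100,100,100,100
Ca_cyt,0.02,,,,,,,
Ca_out,0.1,,,,,,,
G_Cl_max,10,4.0,1.2,30,4.0,4.0,5.0,9.0
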