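d_cap_m: 5.0e-05
r_m: 2.5e-06
F: 1.0
Dose_umol: 0.5
Vd_L: 0.2
ka_per_s: 0.0002
ke_per_s: 5.0e-05
v_blood_m_per_s: 0.0005
D_star_m2_per_s: 5.0e-11
v_ecf_m_per_s: 5.0e-07
P_m_per_s: 1.0e-08
Tm_in_umol_per_s: 0.0
Km_in_umol_per_L: 100.0
Tm_out_umol_per_s: 0.0
Km_out_umol_per_L: 100.0
SA_BBB_m2: 1.0e-10
B1max_umol_per_L: 0.05
k1on_per_umol_L_s: 1.0
k1off_per_s: 0.01
B2max_umol_per_L: 50.0
k2on_per_umol_L_s: 0.01
k2off_per_s: 1.0
mesh:
  n: 18
solver:
  t_end_s: 100000.0
  rtol: 1.0e-06
  atol: 1.0e-10
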