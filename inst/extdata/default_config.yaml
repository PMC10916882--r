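# Six-mass model defaults (interface units: g, N/m, Pa, cm, mm, ms).
# Masses and anchor stiffnesses are per longitudinal section (hence /3).
mass_bottom: 0.04166666666666666   # 0.125/3 g
mass_top: 0.008333333333333333     # 0.025/3 g
k_a_bottom: 26.666666666666668     # 80/3 N/m
k_a_top: 2.6666666666666665        # 8/3 N/m
p_s: 800.0                         # Pa
xi_c: 1.0
xi_l: 0.2
k_v: 1000.0                        # N/m (1 N/mm; vertical pair coupling)
r_a: 6.666666666666667e-05         # 0.0002/3 Ns/m
eta: 100.0                         # 1/cm^2
ell_l: 0.5                         # cm
ell_v: 0.2                         # cm
vf_length: 2.0                     # cm (= 4 * ell_l)
anchor_lateral_posterior: 0.05     # mm
anchor_lateral_anterior: 0.0       # mm
dt: 0.25                           # ms
n_steps: 1000
initial_lower_deflection: 1.0      # mm
k_c_factor: 3.0
smooth_eps: 1.0                    # mm
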