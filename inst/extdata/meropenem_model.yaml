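# Fitted meropenem population PK parameters (critically ill adults).
# CL (L/h) = theta_cl * (1 + theta_cov * (CE - ce_ref)), CE = CKD-EPI eGFR.
theta_cl: 6.37
theta_cov: 0.00925
ce_ref: 91.57
vc: 9.07
q: 10.7
vp: 7.91
omega_cl: 0.314
omega_vc: 0.436
omega_vp: 0.366
sigma_prop: 0.246
power: 0.865
f_unbound: 0.98
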