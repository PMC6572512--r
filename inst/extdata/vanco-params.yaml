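# Final population estimates: two-compartment vancomycin model with renal
# covariates (Korean TDM population, 220 patients / 1020 observations).
# CL (L/h) = theta1 * (CLCR/ref_clcr)^theta2 for patients not on HD/CRRT;
# V2 (L)   = theta3 * (WT/ref_wt).
# omega_*_cv are between-subject CV%, sigma_* residual standard deviations.
theta1: 2.82
theta2: 0.836
cl_crrt: 0.716
cl_hd: 0.334
v1: 31.8
q: 11.7
theta3: 75.4
omega_cl_cv: 99.2
omega_v2_cv: 49.2
sigma_add: 0.0
sigma_prop: 0.253
ref_clcr: 72.0
ref_wt: 60.0
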