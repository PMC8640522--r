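# Final population pharmacokinetic parameters for mycophenolic acid in
# adult heart-transplant recipients (two-compartment, first-order lagged
# absorption; apparent oral parameters).
ka_tv: 0.781        # 1/h
cl_tv: 7.36         # L/h, CL/F at the eGFR reference
v2_tv: 5.69         # L, V2/F at the albumin reference
q_tv: 17.0          # L/h
v3_tv: 560.0        # L
tlag_tv: 0.408      # h
f_tv: 0.95          # fixed bioavailability
theta_ppi_f: 0.724  # multiplicative PPI effect on F
theta_egfr_cl: 0.00791  # per mL/min/1.73 m2, linear eGFR effect on CL/F
theta_alb_v2: -7.31     # power exponent of albumin on V2/F
egfr_ref: 57.0      # mL/min/1.73 m2
alb_ref: 40.0       # g/L
iiv_cv:             # between-subject variability, %CV
  ka: 41.5
  cl: 41.2
  v2: 186.5
  q: 33.3
  v3: 189.5
  tlag: 13.1
  f: 22.1
sigma_prop: 0.261   # proportional residual error
sigma_add: 0.144    # mg/L additive residual error
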