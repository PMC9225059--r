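# Default population prior for infliximab q8w maintenance therapy.
# Typical values anchor to reported cohort medians; covariate model is a
# power model on ratios to the reference covariates. Units: L/day, L, kg,
# g/L, days; concentrations in ug/mL.
tv_cl: 0.300      # clearance, L/day
tv_v1: 3.36       # central volume, L
tv_q: 0.134       # intercompartmental clearance, L/day
tv_v2: 1.56       # peripheral volume, L
wt_exp_cl: 0.75   # allometric exponents (weight / ref_weight)
wt_exp_v1: 1.0
wt_exp_q: 0.75
wt_exp_v2: 1.0
alb_exp_cl: -1.1  # albumin exponent on clearance (lower albumin -> faster Cl)
ati_factor_cl: 1.3  # fold-increase in clearance when anti-drug antibodies present
ref_weight: 70.0
ref_albumin: 41.5
omega: [0.30, 0.20, 0.30, 0.20]  # log-scale SD of (cl, v1, q, v2)
sigma_prop: 0.10  # proportional residual error SD
loq: 0.8          # assay limit of quantitation, ug/mL
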