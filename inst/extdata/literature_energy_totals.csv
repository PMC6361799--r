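# Literature-reported MM/PBSA + interaction-entropy binding terms (kcal/mol)
# for the p53/pDIQ peptides bound to MDMX/MDM2, under a standard additive
# force field (AMBER) and a polarized protein-specific charge set (PPC).
# e_pp: mean inter-partner gas-phase interaction energy; minus_t_delta_s:
# interaction-entropy term; dg_sol: total solvation term; *_std: reported
# standard deviations; dg_bind_reported: published total; dg_exp: experiment.
system,force_field,e_pp,e_pp_std,minus_t_delta_s,mts_std,dg_sol,dg_sol_std,dg_bind_reported,dg_exp
p53-MDMX,AMBER,-287.56,5.00,16.91,1.06,241.52,4.25,-29.12,-9.12
p53-MDMX,PPC,-336.96,5.58,18.87,1.20,290.65,4.42,-27.44,-9.12
p53-MDM2,AMBER,-480.66,6.04,21.45,0.68,432.26,5.04,-26.95,-9.20
p53-MDM2,PPC,-536.69,6.90,25.88,1.35,481.89,5.44,-28.93,-9.20
pDIQ-MDMX,AMBER,-201.31,4.18,11.82,0.68,163.05,3.27,-26.44,-9.5
pDIQ-MDMX,PPC,-237.69,4.65,13.14,0.73,196.33,3.72,-28.22,-9.5
pDIQ-MDM2,AMBER,-372.41,4.81,14.47,0.69,320.47,3.49,-37.47,-11.0
pDIQ-MDM2,PPC,-402.49,5.39,19.66,1.60,351.71,4.30,-31.12,-11.0
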