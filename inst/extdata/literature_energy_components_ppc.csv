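# Literature-reported per-component binding terms (kcal/mol) under the
# polarized protein-specific charge set for the four peptide-receptor
# complexes: van der Waals, electrostatic, polar and nonpolar solvation,
# interaction entropy, the combined electrostatic+polar term as published,
# and the published total binding free energy.
system,vdw,ele,pol,nonpol,minus_t_delta_s,dg_ele_pol_reported,dg_bind_reported
p53-MDMX,-60.30,-276.66,298.71,-8.06,18.87,22.05,-27.44
p53-MDM2,-79.65,-457.04,491.58,-9.69,25.88,24.85,-28.93
pDIQ-MDMX,-61.92,-175.77,204.06,-7.73,13.14,28.29,-28.22
pDIQ-MDM2,-69.50,-332.99,359.84,-8.13,19.66,26.85,-31.12
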