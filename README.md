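# bindscope

End-state binding free-energy analysis of two-chain protein–protein
complexes in R, in the MM/PB(GB)SA family, with the entropic term estimated
by the **interaction-entropy** method.

## Who this is for

Computational structural biologists who have (or can simulate) a snapshot
ensemble of a peptide–receptor or protein–protein complex — for example the
p53/pDIQ peptides bound to the MDMX/MDM2 oncoprotein domains — and want the
standard end-state decomposition of the binding free energy, a per-residue
hot-spot map, and interface hydrogen-bond statistics, without external
MM/PBSA tooling.

## The model

$$\Delta G_{bind} = \underbrace{\langle E_{ele}\rangle + \langle E_{vdW}\rangle - T\Delta S}_{\Delta G_{gas}} \;+\; \underbrace{\Delta G_{pol} + \Delta G_{np}}_{\Delta G_{sol}}$$

* **Gas phase**: exact all-pairs Coulomb + Lennard-Jones interaction energy
  between the two partners, per frame, under the single-trajectory protocol
  (partner coordinates extracted from complex frames), with a per-residue
  decomposition that conserves the frame totals.
* **Entropy**: $-T\Delta S = KT \ln \langle e^{\beta \Delta E^{int}}
  \rangle$, computed from the fluctuations of the interaction-energy series
  in numerically stable log-sum-exp form, with convergence traces,
  per-residue entropies and block uncertainties.
* **Solvation**: Still-type Generalized Born polar term (Hawkins–Cramer–
  Truhlar descreened Born radii, ε 1→80) — or imported per-frame
  Poisson–Boltzmann energies — plus the nonpolar surface term
  $0.00542 \cdot \mathrm{SASA} + 0.92$ on Shrake–Rupley areas.
* **Hydrogen bonds**: inter-partner detection (D···A ≤ 3.5 Å, D–H···A ≥
  120°), occupancies, distance/angle profiles, and the 12-10 potential
  $5.571/R^{12} - 668.580/R^{10}$ at the H···A distance.
* **Reports**: table-style assembly with exact internal identities, ΔΔG
  comparisons between complexes, hot-spot residues (total ≤ −2 kcal/mol),
  and Kabsch-superposed backbone RMSD stability checks.

Because real inputs are MD ensembles, the package also ships a seeded
synthetic system: coarse-grained two-chain dimers with designed hydrogen
bonds and salt bridges, sampled around the reference pose by tethered
Metropolis Monte Carlo — every downstream stage is testable against known
ground truth.

## Worked example

```r
library(bindscope)

spec <- dimer_spec(3, 3, n_designed_hbonds = 2, n_salt_bridges = 1,
                   tether_force_constant = 10, seed = 1)
d   <- build_toy_dimer(spec)
trj <- sample_trajectory(d$topology, d$reference, n_frames = 500, seed = 1)
out <- analyze_binding(trj, solvation_stride = 10, n_points = 240)

out$report
#> binding report:
#>   <E_ele>     -122.24    <E_vdW>      8.32
#>   <E_pp>      -113.93    -TdS         0.70
#>   dG_pol       114.78    dG_np       -1.96
#>   dG_sol       112.82    dG_gas    -113.23
#>   dG_ele+pol    -7.46    dG_bind     -0.41

hbond_table(out$hbonds)
#>   donor hydrogen acceptor  mean_da occupancy_pct mean_energy
#> 1 A:1:N    A:1:H    B:1:O 2.995316          85.8   -1.515198
#> 2 A:2:N    A:2:H    B:2:O 3.036531          79.8   -1.535866

out$hotspots
#>   residue       ele      vdw pol nonpol minus_t_delta_s     total
#> 1 B:3:CHG -122.2427 8.552161   0      0       0.7322825 -112.9583
```

Reading the output: the designed salt bridge dominates the electrostatics
(−122 kcal/mol across a +1/−1 pair at ~3 Å) and is duly the lone hot-spot
residue; the two designed hydrogen bonds are recovered at ~80–86% occupancy
under the loose tether; and the large polar-solvation penalty opposing the
electrostatic attraction — leaving a small net ΔG_bind — is exactly the
compensation pattern seen in real charged interfaces. The report fields
satisfy ΔG_bind = ⟨E_pp⟩ + (−TΔS) + ΔG_sol identically.

Published component tables for the four p53/pDIQ–MDMX/MDM2 complexes ship
with the package and reassemble through the same machinery:

```r
tabs <- literature_binding_tables()
r <- subset(tabs$totals, system == "p53-MDMX" & force_field == "PPC")
rep <- assemble_binding_report(c(total = r$e_pp), r$minus_t_delta_s,
                               c(dg_sol = r$dg_sol))
round(rep$dg_bind, 2)
#> [1] -27.44
```

See `vignettes/binding-free-energy.Rmd` for the full account of the model,
the estimator numerics, and the synthetic-data design.

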