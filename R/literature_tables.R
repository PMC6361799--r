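# Shipped reference data: published MM/PBSA + interaction-entropy energy terms
# for the p53/pDIQ peptides bound to the MDMX and MDM2 oncoprotein domains.
# These are inputs for table arithmetic (report assembly, ddG comparisons),
# not outputs of this package.

#' Literature-reported binding energy terms for p53/pDIQ-MDMX/MDM2
#'
#' Published MM/PBSA + interaction-entropy terms (kcal/mol) for four
#' peptide-receptor complexes: the p53 transactivation peptide and the pDIQ
#' 12-mer inhibitor, each bound to the MDMX and MDM2 oncoprotein domains,
#' under a standard additive force field (AMBER) and a polarized
#' protein-specific charge (PPC) set.
#'
#' @return A list of two data.frames: `totals` (per system and force field:
#'   mean gas-phase interaction energy `e_pp`, `minus_t_delta_s`, `dg_sol`,
#'   their reported standard deviations, the published `dg_bind_reported` and
#'   the experimental `dg_exp`) and `components_ppc` (per system under PPC:
#'   `vdw`, `ele`, `pol`, `nonpol`, `minus_t_delta_s`, the published
#'   `dg_ele_pol_reported` and `dg_bind_reported`).
#' @examples
#' tabs <- literature_binding_tables()
#' r <- with(subset(tabs$totals, system == "p53-MDMX" & force_field == "PPC"),
#'           assemble_binding_report(c(total = e_pp), minus_t_delta_s,
#'                                   c(dg_sol = dg_sol)))
#' round(r$dg_bind, 2)  # -27.44, matching the published total
#' @export
literature_binding_tables <- function() {
  rd <- function(f)
    utils::read.csv(system.file("extdata", f, package = "bindscope",
                                mustWork = TRUE),
                    comment.char = "#", stringsAsFactors = FALSE)
  list(totals = rd("literature_energy_totals.csv"),
       components_ppc = rd("literature_energy_components_ppc.csv"))
}
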