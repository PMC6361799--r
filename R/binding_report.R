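# Assembly of all energy terms into table-style binding reports:
#   dG_gas  = <E_ele> + <E_vdW> + (-TdS)
#   dG_sol  = dG_pol + dG_np
#   dG_bind = dG_gas + dG_sol = <E_pp> + (-TdS) + dG_sol
# plus pairwise ddG comparisons, per-residue contribution tables with hot-spot
# selection, and the backbone-RMSD stability check.

.get_term <- function(x, what) {
  if (is.null(x) || (is.atomic(x) && !is.null(names(x)) && !(what %in% names(x))))
    return(NA_real_)
  if (is.atomic(x) && !is.null(names(x))) return(unname(x[[what]]))
  NA_real_
}

#' Assemble a binding report from gas-phase, entropy and solvation terms
#'
#' Accepts the native outputs of the pipeline stages
#' ([interaction_energy_series()], [interaction_entropy()],
#' [binding_solvation()]) or bare named numerics (e.g. literature-reported
#' component values), and enforces the free-energy identities
#' `dg_sol = dg_pol + dg_np`, `dg_gas = mean_ele + mean_vdw + minus_t_delta_s`
#' and `dg_bind = dg_gas + dg_sol` on the stored values.
#'
#' @param gas Either the list of series from [interaction_energy_series()], or
#'   a named numeric with `ele` and `vdw` (component means) or just `total`
#'   (the mean interaction energy, when the split is not known).
#' @param ie An `"ie_result"` from [interaction_entropy()], or a single number
#'   (-TdS, kcal/mol).
#' @param solv A `"solvation_result"` from [binding_solvation()], or a named
#'   numeric with `dg_pol` and `dg_np`, or just `dg_sol`.
#' @param system_label,force_field_label Labels carried into the report (e.g.
#'   complex name and charge-set name).
#' @param uncertainties Optional named numeric of per-term standard
#'   deviations (`e_pp`, `minus_t_delta_s`, `dg_sol`, ...); filled from the
#'   stage objects when available.
#' @return An object of class `"binding_report"`: list with `mean_ele`,
#'   `mean_vdw`, `mean_gas_interaction`, `minus_t_delta_s`, `dg_pol`, `dg_np`,
#'   `dg_sol`, `dg_gas`, `dg_ele_pol`, `dg_bind`, labels, `temperature`,
#'   `n_frames` and `uncertainties`.
#' @examples
#' r <- assemble_binding_report(gas = c(total = -336.96), ie = 18.87,
#'                              solv = c(dg_sol = 290.65))
#' r$dg_bind  # -27.44
#' @export
assemble_binding_report <- function(gas, ie, solv, system_label = "",
                                    force_field_label = "",
                                    uncertainties = numeric(0)) {
  if (missing(gas) || is.null(gas)) stop("missing term: gas")
  if (missing(ie) || is.null(ie)) stop("missing term: ie")
  if (missing(solv) || is.null(solv)) stop("missing term: solv")

  temperature <- NA_real_
  nf <- NA_integer_
  if (is.list(gas) && inherits(gas$ele, "energy_series")) {
    mean_ele <- mean(gas$ele$values)
    mean_vdw <- mean(gas$vdw$values)
    temperature <- gas$ele$temperature
    nf <- length(gas$ele$values)
  } else if (is.numeric(gas)) {
    mean_ele <- .get_term(gas, "ele")
    mean_vdw <- .get_term(gas, "vdw")
    if (is.na(mean_ele) && is.na(mean_vdw) && !("total" %in% names(gas)))
      stop("missing term: gas means (need 'ele'+'vdw' or 'total')")
  } else stop("missing term: gas (unrecognised form)")
  mean_gas <- if (is.numeric(gas) && "total" %in% names(gas) &&
                  is.na(mean_ele)) unname(gas[["total"]])
              else mean_ele + mean_vdw

  if (inherits(ie, "ie_result")) {
    mts <- ie$minus_t_delta_s
    if (is.na(temperature)) temperature <- ie$temperature
    if (is.na(nf)) nf <- ie$n_frames
    if (!("minus_t_delta_s" %in% names(uncertainties)) && !is.na(ie$block_std))
      uncertainties["minus_t_delta_s"] <- ie$block_std
  } else if (is.numeric(ie) && length(ie) == 1L) {
    mts <- as.numeric(ie)
  } else stop("missing term: ie (unrecognised form)")

  if (inherits(solv, "solvation_result")) {
    dg_pol <- solv$dg_pol; dg_np <- solv$dg_np
  } else if (is.numeric(solv)) {
    dg_pol <- .get_term(solv, "dg_pol")
    dg_np <- .get_term(solv, "dg_np")
    if (is.na(dg_pol) && is.na(dg_np) && !("dg_sol" %in% names(solv)))
      stop("missing term: solvation (need 'dg_pol'+'dg_np' or 'dg_sol')")
  } else stop("missing term: solvation (unrecognised form)")
  dg_sol <- if (is.numeric(solv) && "dg_sol" %in% names(solv) && is.na(dg_pol))
    unname(solv[["dg_sol"]]) else dg_pol + dg_np

  dg_gas <- mean_gas + mts
  structure(list(
    system_label = system_label, force_field_label = force_field_label,
    mean_ele = mean_ele, mean_vdw = mean_vdw,
    mean_gas_interaction = mean_gas,
    minus_t_delta_s = mts,
    dg_pol = dg_pol, dg_np = dg_np, dg_sol = dg_sol,
    dg_gas = dg_gas,
    dg_ele_pol = mean_ele + dg_pol,
    dg_bind = dg_gas + dg_sol,
    temperature = temperature, n_frames = nf,
    uncertainties = uncertainties), class = "binding_report")
}

#' @export
print.binding_report <- function(x, ...) {
  lab <- paste(c(if (nzchar(x$system_label)) x$system_label,
                 if (nzchar(x$force_field_label)) x$force_field_label),
               collapse = ", ")
  cat("binding report", if (nzchar(lab)) paste0(" (", lab, ")"), ":\n", sep = "")
  fmt <- function(v) ifelse(is.na(v), "    NA", sprintf("%8.2f", v))
  cat("  <E_ele>   ", fmt(x$mean_ele), "   <E_vdW> ", fmt(x$mean_vdw), "\n")
  cat("  <E_pp>    ", fmt(x$mean_gas_interaction),
      "   -TdS    ", fmt(x$minus_t_delta_s), "\n")
  cat("  dG_pol    ", fmt(x$dg_pol), "   dG_np   ", fmt(x$dg_np), "\n")
  cat("  dG_sol    ", fmt(x$dg_sol), "   dG_gas  ", fmt(x$dg_gas), "\n")
  cat("  dG_ele+pol", fmt(x$dg_ele_pol), "   dG_bind ", fmt(x$dg_bind), "\n")
  invisible(x)
}

#' Per-term difference between two binding reports
#'
#' Returns `report_b - report_a` for every energy term (second argument minus
#' first), the convention used when listing the more strongly binding system
#' second.
#'
#' @param report_a,report_b Two `"binding_report"` objects at the same
#'   temperature (when both record one).
#' @return Named numeric vector of differences for `mean_ele`, `mean_vdw`,
#'   `mean_gas_interaction`, `minus_t_delta_s`, `dg_pol`, `dg_np`, `dg_sol`,
#'   `dg_gas`, `dg_ele_pol`, `dg_bind` (kcal/mol).
#' @export
delta_delta_g <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "binding_report"),
            inherits(report_b, "binding_report"))
  if (!is.na(report_a$temperature) && !is.na(report_b$temperature) &&
      report_a$temperature != report_b$temperature)
    stop("reports are at different temperatures")
  terms <- c("mean_ele", "mean_vdw", "mean_gas_interaction",
             "minus_t_delta_s", "dg_pol", "dg_np", "dg_sol", "dg_gas",
             "dg_ele_pol", "dg_bind")
  vapply(terms, function(t) report_b[[t]] - report_a[[t]], numeric(1))
}

#' Build a per-residue contribution table
#'
#' Combines per-residue gas-phase means, per-residue entropy, and optional
#' per-residue solvation terms into the decomposition table used for hot-spot
#' analysis; `total` is the sum of the five components.
#'
#' @param res_series Output of [per_residue_interaction_series()].
#' @param res_entropy Named numeric from [per_residue_entropy()] (same
#'   residues); defaults to zero when omitted.
#' @param pol,nonpol Optional named numerics of per-residue polar/nonpolar
#'   solvation contributions (kcal/mol); default zero.
#' @return A data.frame with columns `residue`, `ele`, `vdw`, `pol`,
#'   `nonpol`, `minus_t_delta_s`, `total`.
#' @export
residue_contributions <- function(res_series, res_entropy = NULL,
                                  pol = NULL, nonpol = NULL) {
  res <- names(res_series)
  pick <- function(v, r) if (is.null(v) || !(r %in% names(v))) 0 else unname(v[[r]])
  out <- do.call(rbind, lapply(res, function(r) {
    ele <- mean(res_series[[r]]$ele$values)
    vdw <- mean(res_series[[r]]$vdw$values)
    mts <- pick(res_entropy, r)
    p <- pick(pol, r); np <- pick(nonpol, r)
    data.frame(residue = r, ele = ele, vdw = vdw, pol = p, nonpol = np,
               minus_t_delta_s = mts,
               total = ele + vdw + p + np + mts,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Select hot-spot residues from a contribution table
#'
#' A hot spot contributes at least as favourably as `threshold` (default
#' -2 kcal/mol) to binding.
#'
#' @param contributions Data.frame from [residue_contributions()] (needs
#'   columns `residue` and `total`).
#' @param threshold Cutoff in kcal/mol; residues with `total <= threshold`
#'   are kept.
#' @return The selected rows sorted ascending by `total` (strongest first).
#' @export
hotspot_residues <- function(contributions, threshold = -2) {
  stopifnot(is.data.frame(contributions),
            all(c("residue", "total") %in% names(contributions)))
  out <- contributions[contributions$total <= threshold, , drop = FALSE]
  out <- out[order(out$total), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Backbone RMSD of every frame against a reference structure
#'
#' Root-mean-square deviation of the selected backbone atoms after optimal
#' least-squares (Kabsch) superposition onto the reference, one value per
#' frame.
#'
#' @param trj A [trajectory()].
#' @param reference `n_atoms x 3` reference coordinates.
#' @param selection Atom names to include (default N, CA, C); at least 3
#'   selected atoms are required.
#' @param fit If `TRUE` (default) superpose before measuring; `FALSE`
#'   measures raw deviation in the given coordinates.
#' @return Numeric vector of per-frame RMSD values, Angstrom.
#' @export
backbone_rmsd <- function(trj, reference, selection = c("N", "CA", "C"),
                          fit = TRUE) {
  stopifnot(inherits(trj, "trajectory"))
  sel <- which(trj$topology$atoms$atom_name %in% selection)
  if (length(sel) < 3)
    stop("fewer than 3 atoms selected for RMSD (", length(sel), ")")
  reference <- as.matrix(reference)
  ref_sel <- reference[sel, , drop = FALSE]
  ref_xyz <- as.vector(t(ref_sel))
  nsel <- length(sel)
  nf <- n_frames(trj)
  vapply(seq_len(nf), function(k) {
    mob <- frame_coords(trj, k)[sel, , drop = FALSE]
    if (fit) {
      fitted <- bio3d::fit.xyz(ref_xyz, matrix(as.vector(t(mob)), nrow = 1),
                               fixed.inds = seq_len(3 * nsel),
                               mobile.inds = seq_len(3 * nsel))
      mob <- matrix(fitted[1, ], ncol = 3, byrow = TRUE)
    }
    sqrt(mean(rowSums((mob - ref_sel)^2)))
  }, numeric(1))
}

#' End-to-end binding analysis of a two-chain trajectory
#'
#' Convenience driver chaining the pipeline stages: inter-partner interaction
#' energies, interaction entropy, implicit-solvent terms, hydrogen bonds, and
#' the per-residue decomposition of the selected partner, assembled into one
#' binding report.
#'
#' @param trj A [trajectory()].
#' @param solvation_stride Frame stride for the solvation terms (the entropy
#'   estimator always uses every frame).
#' @param decompose_side Partner whose residues are decomposed.
#' @param criteria Hydrogen-bond criteria, see [hbond_criteria()].
#' @param hotspot_threshold Hot-spot cutoff, kcal/mol.
#' @param ... Further arguments passed to [binding_solvation()].
#' @param system_label,force_field_label Report labels.
#' @return A list with `report` (a `"binding_report"`), `gas` (the three
#'   energy series), `ie` (the `"ie_result"`), `solvation`, `hbonds`,
#'   `residue_table` and `hotspots`.
#' @export
analyze_binding <- function(trj, solvation_stride = 1,
                            decompose_side = "partner2",
                            criteria = hbond_criteria(),
                            hotspot_threshold = -2,
                            system_label = "", force_field_label = "", ...) {
  stopifnot(inherits(trj, "trajectory"))
  gas <- interaction_energy_series(trj)
  ie <- interaction_entropy(gas$total)
  solv <- binding_solvation(trj, stride = solvation_stride, ...)
  report <- assemble_binding_report(gas, ie, solv,
                                    system_label = system_label,
                                    force_field_label = force_field_label)
  hbonds <- detect_hbonds(trj, criteria)
  res_series <- per_residue_interaction_series(trj, decompose_side)
  res_entropy <- per_residue_entropy(res_series)
  res_table <- residue_contributions(res_series, res_entropy)
  list(report = report, gas = gas, ie = ie, solvation = solv,
       hbonds = hbonds, residue_table = res_table,
       hotspots = hotspot_residues(res_table, hotspot_threshold))
}
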