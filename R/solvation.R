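# Implicit-solvent terms. Polar: a Still-style Generalized Born energy with
# Hawkins-Cramer-Truhlar pairwise-descreened effective Born radii (a surrogate
# for a grid Poisson-Boltzmann solver; externally computed PB energies can be
# imported instead). Nonpolar: gamma * SASA + beta on Shrake-Rupley solvent
# accessible surface areas.

# Deterministic golden-spiral point set on the unit sphere.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Places a deterministic golden-spiral point set on each atom's solvent
#' sphere (radius `r_atom + probe`) and counts the points not buried inside
#' any neighbouring solvent sphere. Per-atom area is
#' `4*pi*(r+probe)^2 * accessible/n_points`.
#'
#' @param frame `n_atoms x 3` coordinate matrix (Angstrom).
#' @param radii Per-atom van der Waals radii (Angstrom, > 0); see
#'   [element_radii()].
#' @param probe Probe radius, Angstrom (water: 1.4).
#' @param n_points Sphere points per atom (>= 16; 960 gives ~1-2% accuracy).
#' @return Numeric vector of per-atom accessible areas, Angstrom^2.
#' @examples
#' shrake_rupley_sasa(matrix(0, 1, 3), radii = 1.6)  # 4*pi*3^2 = 113.097
#' @export
shrake_rupley_sasa <- function(frame, radii, probe = 1.4, n_points = 960) {
  frame <- as.matrix(frame)
  if (ncol(frame) != 3L) stop("frame must be an n x 3 coordinate matrix")
  n <- nrow(frame)
  radii <- rep_len(radii, n)
  if (any(radii <= 0)) stop("atomic radii must be > 0")
  if (n_points < 16) stop("n_points must be >= 16")
  unit <- .sphere_points(n_points)
  solv <- radii + probe
  out <- numeric(n)
  d2 <- as.matrix(stats::dist(frame))^2
  for (i in seq_len(n)) {
    neigh <- which(d2[i, ] < (solv[i] + solv)^2 & seq_len(n) != i)
    pts <- unit * solv[i]
    pts <- sweep(pts, 2, frame[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in neigh) {
      dx <- pts[, 1] - frame[j, 1]
      dy <- pts[, 2] - frame[j, 2]
      dz <- pts[, 3] - frame[j, 3]
      accessible <- accessible & (dx * dx + dy * dy + dz * dz >= solv[j]^2)
      if (!any(accessible)) break
    }
    out[i] <- 4 * pi * solv[i]^2 * sum(accessible) / n_points
  }
  out
}

#' Nonpolar solvation free energy from SASA
#'
#' The linear surface-area model `gamma * SASA + beta` with
#' `gamma = 0.00542 kcal/(mol A^2)` and `beta = 0.92 kcal/mol` by default.
#' Note the constant offset: in the binding difference
#' `np(complex) - np(p1) - np(p2)` the three offsets leave a residual
#' `-beta`; see [binding_solvation()] for the switch controlling this.
#'
#' @param sasa_total Total SASA in Angstrom^2 (>= 0).
#' @param gamma,beta Surface tension and offset coefficients.
#' @return Nonpolar solvation energy, kcal/mol.
#' @export
nonpolar_term <- function(sasa_total, gamma = 0.00542, beta = 0.92) {
  if (any(sasa_total < 0)) stop("SASA must be >= 0")
  gamma * sasa_total + beta
}

# HCT pairwise-descreening effective Born radii. rho: intrinsic radii
# (vdW - offset); scale: per-atom descreening scale factors.
.born_radii <- function(frame, rho, scale) {
  n <- nrow(frame)
  if (n == 1L) return(rho)
  d <- as.matrix(stats::dist(frame))
  inv_a <- 1 / rho
  clamped <- FALSE
  for (i in seq_len(n)) {
    s <- scale[-i] * rho[-i]
    r <- d[i, -i]
    keep <- (r + s) > rho[i]
    if (!any(keep)) next
    r <- r[keep]; s <- s[keep]
    L <- pmax(abs(r - s), rho[i])
    U <- r + s
    integral <- 0.5 * (1 / L - 1 / U +
                         (r / 4) * (1 / U^2 - 1 / L^2) +
                         (1 / (2 * r)) * log(L / U) +
                         (s^2 / (4 * r)) * (1 / L^2 - 1 / U^2))
    inv_a[i] <- inv_a[i] - sum(integral)
    if (inv_a[i] <= 0) {
      inv_a[i] <- 1 / rho[i]
      clamped <- TRUE
    }
  }
  a <- 1 / inv_a
  if (clamped)
    message("GB: nonpositive Born radius after descreening; clamped to intrinsic radius")
  pmax(a, rho)
}

# Still pairwise interpolation f_GB, full n x n matrix (diagonal = a_i).
.f_gb <- function(frame, a) {
  d2 <- as.matrix(stats::dist(frame))^2
  aa <- outer(a, a)
  sqrt(d2 + aa * exp(-d2 / (4 * aa)))
}

#' Generalized Born polar solvation energy
#'
#' Still-style GB energy
#' `-1/2 * 332.0637 * (1/eps_in - 1/eps_out) * sum_ij q_i q_j / f_GB(r_ij)`
#' over all pairs (including self terms), with
#' `f_GB = sqrt(r^2 + a_i a_j exp(-r^2 / (4 a_i a_j)))` and effective Born
#' radii `a_i` from Hawkins-Cramer-Truhlar pairwise descreening, bounded below
#' by the intrinsic radii.
#'
#' @param frame `n_atoms x 3` coordinate matrix (Angstrom).
#' @param top A [topology()] (supplies charges and elements).
#' @param selection Atom indices to include (default: all atoms). The energy
#'   of an isolated partner is obtained by selecting only its atoms.
#' @param eps_in,eps_out Internal and external dielectric constants
#'   (default 1 and 80).
#' @param intrinsic_radii Optional per-selected-atom intrinsic radii
#'   (Angstrom); default Bondi-style element radii minus a 0.09 A offset.
#' @return Polar solvation energy, kcal/mol.
#' @examples
#' # Born ion: q = 1, radius 2 A, eps 1 -> 80 gives -81.978 kcal/mol
#' top1 <- topology(data.frame(
#'   atom_name = "NA", element = "NA", residue_number = 1,
#'   residue_name = "ION", chain_id = "A", charge = 1, rmin_half = 0,
#'   epsilon = 0, donor_heavy = FALSE, acceptor = FALSE,
#'   polar_hydrogen = FALSE, bonded_heavy = NA_integer_),
#'   "A", character(0), 300)
#' \dontrun{gb_polar(matrix(0, 1, 3), top1, intrinsic_radii = 2)}
#' @export
gb_polar <- function(frame, top, selection = NULL, eps_in = 1, eps_out = 80,
                     intrinsic_radii = NULL) {
  stopifnot(inherits(top, "topology"))
  frame <- as.matrix(frame)
  if (is.null(selection)) selection <- seq_len(nrow(top$atoms))
  if (!length(selection)) stop("selection must be non-empty")
  a <- top$atoms[selection, , drop = FALSE]
  x <- frame[selection, , drop = FALSE]
  q <- a$charge
  if (all(q == 0)) return(0)
  if (is.null(intrinsic_radii)) {
    rho <- element_radii(a$element) - .gb_radius_offset
  } else {
    rho <- rep_len(intrinsic_radii, length(selection))
  }
  if (any(rho <= 0)) stop("intrinsic radii must be > 0")
  sc <- .gb_scale_factors[toupper(a$element)]
  sc[is.na(sc)] <- .default_gb_scale
  born <- .born_radii(x, rho, sc)
  f <- .f_gb(x, born)
  -0.5 * .kCoulomb * (1 / eps_in - 1 / eps_out) * sum(outer(q, q) / f)
}

#' Single-trajectory binding solvation terms
#'
#' For each selected frame, computes the polar and nonpolar solvation
#' contributions to binding under the single-trajectory protocol: the partner
#' coordinates are extracted from the complex frame, so
#' `dG_pol = pol(complex) - pol(p1) - pol(p2)` and likewise for the nonpolar
#' term. The polar term comes from the internal GB model, or from an external
#' per-frame series (e.g. a Poisson-Boltzmann solver run outside R).
#'
#' @param trj A [trajectory()].
#' @param stride Keep every `stride`-th frame (>= 1). Solvation is usually
#'   evaluated on a subset of snapshots (around 100), while the
#'   interaction-entropy estimator uses all frames.
#' @param polar_source `"gb_internal"` or `"external_file"`.
#' @param external_polar When `polar_source = "external_file"`: a numeric
#'   vector of per-selected-frame `dG_pol` values, or a path to a CSV file
#'   with columns `frame, dg_pol` (or `frame, complex, p1, p2`). Length must
#'   equal the number of selected frames.
#' @param probe,n_points SASA parameters, see [shrake_rupley_sasa()].
#' @param gamma,beta Nonpolar coefficients, see [nonpolar_term()].
#' @param drop_np_offset If `TRUE`, the `beta` offsets are assumed to cancel
#'   in the binding difference (`dG_np = gamma * dSASA`); the default `FALSE`
#'   applies the offset per species, leaving `gamma * dSASA - beta`.
#' @param eps_in,eps_out GB dielectrics.
#' @return An object of class `"solvation_result"`: list with `frames`
#'   (data.frame `frame, dg_pol, dg_np, sasa_complex, sasa_p1, sasa_p2`),
#'   `dg_pol`, `dg_np`, `dg_sol` (means), `dg_pol_std`, `dg_np_std` (block or
#'   plain SDs across frames), and `source`.
#' @export
binding_solvation <- function(trj, stride = 1,
                              polar_source = c("gb_internal", "external_file"),
                              external_polar = NULL,
                              probe = 1.4, n_points = 960,
                              gamma = 0.00542, beta = 0.92,
                              drop_np_offset = FALSE,
                              eps_in = 1, eps_out = 80) {
  stopifnot(inherits(trj, "trajectory"))
  polar_source <- match.arg(polar_source)
  if (stride < 1) stop("stride must be >= 1")
  top <- trj$topology
  sel_frames <- seq(1, n_frames(trj), by = stride)
  nf <- length(sel_frames)

  ext <- NULL
  if (polar_source == "external_file") {
    if (is.null(external_polar))
      stop("polar_source = 'external_file' requires external_polar")
    if (is.character(external_polar)) {
      tab <- utils::read.csv(external_polar, comment.char = "#")
      ext <- if ("dg_pol" %in% names(tab)) tab$dg_pol
             else tab$complex - tab$p1 - tab$p2
    } else ext <- as.numeric(external_polar)
    if (length(ext) != nf)
      stop("external polar series has ", length(ext), " values; ", nf,
           " selected frames")
  }

  radii <- element_radii(top$atoms$element)
  i1 <- top$partner1
  i2 <- top$partner2
  dg_pol <- dg_np <- s_cx <- s_p1 <- s_p2 <- numeric(nf)
  for (k in seq_len(nf)) {
    fr <- frame_coords(trj, sel_frames[k])
    sasa <- shrake_rupley_sasa(fr, radii, probe = probe, n_points = n_points)
    s_cx[k] <- sum(sasa)
    s_p1[k] <- sum(shrake_rupley_sasa(fr[i1, , drop = FALSE], radii[i1],
                                      probe = probe, n_points = n_points))
    s_p2[k] <- sum(shrake_rupley_sasa(fr[i2, , drop = FALSE], radii[i2],
                                      probe = probe, n_points = n_points))
    np <- function(s) nonpolar_term(s, gamma = gamma, beta = beta)
    dg_np[k] <- if (drop_np_offset) gamma * (s_cx[k] - s_p1[k] - s_p2[k])
                else np(s_cx[k]) - np(s_p1[k]) - np(s_p2[k])
    dg_pol[k] <- if (polar_source == "external_file") ext[k]
      else gb_polar(fr, top, eps_in = eps_in, eps_out = eps_out) -
           gb_polar(fr, top, selection = i1, eps_in = eps_in, eps_out = eps_out) -
           gb_polar(fr, top, selection = i2, eps_in = eps_in, eps_out = eps_out)
  }

  bsd <- function(x) {
    if (length(x) >= 20) block_uncertainty(x, statistic = "mean")
    else if (length(x) >= 2) stats::sd(x) else NA_real_
  }
  structure(list(
    frames = data.frame(frame = sel_frames, dg_pol = dg_pol, dg_np = dg_np,
                        sasa_complex = s_cx, sasa_p1 = s_p1, sasa_p2 = s_p2),
    dg_pol = mean(dg_pol), dg_np = mean(dg_np),
    dg_sol = mean(dg_pol) + mean(dg_np),
    dg_pol_std = bsd(dg_pol), dg_np_std = bsd(dg_np),
    source = polar_source), class = "solvation_result")
}

#' @export
print.solvation_result <- function(x, ...) {
  cat(sprintf("solvation over %d frames (%s):\n", nrow(x$frames), x$source))
  cat(sprintf("  dG_pol = %.2f, dG_np = %.2f, dG_sol = %.2f kcal/mol\n",
              x$dg_pol, x$dg_np, x$dg_sol))
  invisible(x)
}
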