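# Inter-partner molecular-mechanics interaction energies: pairwise Coulomb and
# Lennard-Jones sums between the two binding partners, per frame, with a
# per-residue decomposition. All pairs are summed exactly (no cutoff, no
# periodic images); intra-partner pairs never enter, which is what makes the
# single-trajectory interpretation of the interaction energy exact.

# Lorentz-Berthelot-style AMBER combination: R_min,ij = rmin_half_i +
# rmin_half_j (each already R_min/2), eps_ij = sqrt(eps_i * eps_j).
.lj_combine <- function(rmin_half_i, rmin_half_j, eps_i, eps_j) {
  list(rmin = rmin_half_i + rmin_half_j, eps = sqrt(eps_i * eps_j))
}

.energy_components <- function(ele, vdw) {
  structure(list(ele = ele, vdw = vdw, total = ele + vdw),
            class = "energy_components")
}

#' @export
print.energy_components <- function(x, ...) {
  cat(sprintf("ele %.6f + vdw %.6f = total %.6f kcal/mol\n",
              x$ele, x$vdw, x$total))
  invisible(x)
}

#' Coulomb + Lennard-Jones energy of one atom pair
#'
#' Electrostatics: `332.0637 * q_i * q_j / r` (kcal/mol with charges in e and
#' r in Angstrom). van der Waals: AMBER R_min form
#' `eps_ij * ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6)` with Lorentz-Berthelot-style
#' combination of the per-atom `rmin_half` and `epsilon` parameters.
#'
#' @param atom_i,atom_j Single atom records: lists or one-row data.frames with
#'   fields `charge`, `rmin_half`, `epsilon`.
#' @param r Distance in Angstrom; must be > 0.
#' @return An `"energy_components"` list with `ele`, `vdw`, `total` (kcal/mol),
#'   where `total = ele + vdw` exactly as computed.
#' @examples
#' a <- list(charge = 1, rmin_half = 0, epsilon = 0)
#' b <- list(charge = -1, rmin_half = 0, epsilon = 0)
#' pair_energy(a, b, 3.320637)$ele  # -100 kcal/mol
#' @export
pair_energy <- function(atom_i, atom_j, r) {
  if (!is.numeric(r) || r <= 0) stop("pair distance must be > 0 (coincident atoms?)")
  ele <- .kCoulomb * atom_i$charge * atom_j$charge / r
  lj <- .lj_combine(atom_i$rmin_half, atom_j$rmin_half,
                    atom_i$epsilon, atom_j$epsilon)
  sr6 <- (lj$rmin / r)^6
  vdw <- lj$eps * (sr6^2 - 2 * sr6)
  .energy_components(ele, vdw)
}

# Vectorised inter-partner energy matrices for one frame. Returns the n1 x n2
# electrostatic and vdW pair-energy matrices (row = partner1 atom).
.pair_matrices <- function(frame, top) {
  i1 <- top$partner1
  i2 <- top$partner2
  x1 <- frame[i1, , drop = FALSE]
  x2 <- frame[i2, , drop = FALSE]
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  d2[d2 < 0] <- 0  # numerical floor
  r <- sqrt(d2)
  if (any(r == 0)) {
    bad <- which(r == 0, arr.ind = TRUE)[1, ]
    stop("coincident inter-partner atoms: ",
         .atom_label(top$atoms, i1[bad[1]]), " and ",
         .atom_label(top$atoms, i2[bad[2]]))
  }
  a <- top$atoms
  ele <- .kCoulomb * outer(a$charge[i1], a$charge[i2]) / r
  rmin <- outer(a$rmin_half[i1], a$rmin_half[i2], "+")
  eps <- outer(sqrt(a$epsilon[i1]), sqrt(a$epsilon[i2]))
  sr6 <- (rmin / r)^6
  vdw <- eps * (sr6^2 - 2 * sr6)
  list(ele = ele, vdw = vdw)
}

#' Total inter-partner interaction energy of one frame
#'
#' Sums [pair_energy()] over every (partner1 atom, partner2 atom) pair, with
#' no distance cutoff. Intra-partner pairs are excluded by construction.
#'
#' @param frame An `n_atoms x 3` coordinate matrix (Angstrom).
#' @param top A [topology()].
#' @return An `"energy_components"` list (`ele`, `vdw`, `total`, kcal/mol).
#' @export
group_interaction_energy <- function(frame, top) {
  stopifnot(inherits(top, "topology"))
  frame <- as.matrix(frame)
  if (!all(dim(frame) == c(nrow(top$atoms), 3)))
    stop("frame does not match topology atom count")
  m <- .pair_matrices(frame, top)
  .energy_components(sum(m$ele), sum(m$vdw))
}

#' Per-frame inter-partner interaction-energy series
#'
#' @param trj A [trajectory()].
#' @return A list of three [energy_series()]: `ele`, `vdw`, `total`, one value
#'   per frame. The mean of `total` is the average protein-protein interaction
#'   energy that enters the gas-phase binding term and the interaction-entropy
#'   estimator.
#' @export
interaction_energy_series <- function(trj) {
  stopifnot(inherits(trj, "trajectory"))
  nf <- n_frames(trj)
  ele <- vdw <- numeric(nf)
  for (k in seq_len(nf)) {
    m <- .pair_matrices(frame_coords(trj, k), trj$topology)
    ele[k] <- sum(m$ele)
    vdw[k] <- sum(m$vdw)
  }
  tmp <- trj$topology$temperature
  list(ele = energy_series(ele, "ele", trj$frame_interval, tmp),
       vdw = energy_series(vdw, "vdw", trj$frame_interval, tmp),
       total = energy_series(ele + vdw, "total", trj$frame_interval, tmp))
}

#' Per-residue decomposition of the inter-partner interaction energy
#'
#' For every residue of the selected partner, the per-frame sum of pair
#' energies between that residue's atoms and all atoms of the other partner.
#' Each frame's residue values are rows of the same pair-energy matrix that
#' defines the total, so they conserve the frame total to floating-point
#' accumulation error.
#'
#' @param trj A [trajectory()].
#' @param side `"partner1"` or `"partner2"`: the partner whose residues are
#'   decomposed (decompose receptor residues against the peptide by selecting
#'   the receptor side).
#' @return A named list keyed by residue label (`chain:resnum:resname`), each
#'   element a list of [energy_series()] `ele`, `vdw`, `total`.
#' @export
per_residue_interaction_series <- function(trj, side = c("partner1", "partner2")) {
  stopifnot(inherits(trj, "trajectory"))
  side <- match.arg(side)
  top <- trj$topology
  sel <- if (side == "partner1") top$partner1 else top$partner2
  if (!length(sel)) stop("empty residue selection for ", side)
  keys <- .residue_key(top$atoms)[sel]
  groups <- factor(keys, levels = unique(keys))
  nf <- n_frames(trj)
  res_names <- levels(groups)
  ele <- vdw <- matrix(0, nrow = length(res_names), ncol = nf,
                       dimnames = list(res_names, NULL))
  for (k in seq_len(nf)) {
    m <- .pair_matrices(frame_coords(trj, k), top)
    if (side == "partner1") {
      ele[, k] <- rowsum(rowSums(m$ele), groups)[res_names, ]
      vdw[, k] <- rowsum(rowSums(m$vdw), groups)[res_names, ]
    } else {
      ele[, k] <- rowsum(colSums(m$ele), groups)[res_names, ]
      vdw[, k] <- rowsum(colSums(m$vdw), groups)[res_names, ]
    }
  }
  tmp <- top$temperature
  out <- lapply(res_names, function(rn) {
    list(ele = energy_series(ele[rn, ], paste0(rn, ":ele"),
                             trj$frame_interval, tmp),
         vdw = energy_series(vdw[rn, ], paste0(rn, ":vdw"),
                             trj$frame_interval, tmp),
         total = energy_series(ele[rn, ] + vdw[rn, ], paste0(rn, ":total"),
                               trj$frame_interval, tmp))
  })
  names(out) <- res_names
  out
}
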