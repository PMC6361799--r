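# Inter-partner hydrogen bonds: geometric detection (donor-acceptor distance
# plus donor-H...acceptor angle), per-bond occupancy over a trajectory, and a
# 12-10 potential evaluated at the hydrogen-acceptor distance.

#' Hydrogen-bond geometric criteria
#'
#' Defaults: donor-heavy to acceptor distance <= 3.5 A and donor-H...acceptor
#' angle >= 120 degrees — consistent with the 2.6-3.0 A donor-acceptor
#' distances and >120 degree angles typical of stable interface hydrogen
#' bonds.
#'
#' @param max_da_distance Maximum donor-acceptor distance, Angstrom (> 0).
#' @param min_dha_angle Minimum donor-H...acceptor angle at the hydrogen,
#'   degrees, in (0, 180].
#' @return An object of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, min_dha_angle = 120) {
  if (max_da_distance <= 0) stop("max_da_distance must be > 0")
  if (min_dha_angle <= 0 || min_dha_angle > 180)
    stop("min_dha_angle must lie in (0, 180]")
  structure(list(max_da_distance = max_da_distance,
                 min_dha_angle = min_dha_angle),
            class = "hbond_criteria")
}

#' 12-10 hydrogen-bond potential
#'
#' `E(R) = 5.571 / R^12 - 668.580 / R^10` (kcal/mol), with `R` the
#' hydrogen-acceptor distance in Angstrom. With these coefficients the
#' repulsive 12-term is negligible over physical distances: the minimum sits
#' at `sqrt(12 * 5.571 / (10 * 668.580)) ~ 0.1 A`, so the energy is strictly
#' negative and increases monotonically toward zero on the physical range.
#'
#' @param r_ha Hydrogen-acceptor distance(s), Angstrom (> 0).
#' @param alpha,beta 12- and 10-term coefficients.
#' @return Energy in kcal/mol (vectorised).
#' @examples
#' hbond_energy(c(1.8, 2.0))
#' @export
hbond_energy <- function(r_ha, alpha = 5.571, beta = 668.580) {
  if (any(r_ha <= 0)) stop("hydrogen-acceptor distance must be > 0")
  alpha / r_ha^12 - beta / r_ha^10
}

.angle_deg <- function(v1, v2) {
  # angle between row-wise vectors, degrees
  num <- rowSums(v1 * v2)
  den <- sqrt(rowSums(v1^2) * rowSums(v2^2))
  cosang <- pmin(1, pmax(-1, num / den))
  acos(cosang) * 180 / pi
}

#' Detect inter-partner hydrogen bonds along a trajectory
#'
#' Candidate triples are every (donor heavy, bonded polar hydrogen, acceptor)
#' combination with donor and acceptor on opposite partners, in both
#' directions. A frame satisfies the bond when the donor-acceptor distance
#' and donor-H...acceptor angle pass `criteria`; a triple is reported when it
#' satisfies the criteria in at least `occupancy_floor` percent of frames.
#' Mean distances and mean 12-10 energy are computed over satisfying frames
#' only.
#'
#' @param trj A [trajectory()] whose topology annotates donors, polar
#'   hydrogens and acceptors.
#' @param criteria An [hbond_criteria()].
#' @param occupancy_floor Minimum occupancy (percent) for a bond to be
#'   reported.
#' @return A list of `"hbond_record"` objects, each with `donor`, `hydrogen`,
#'   `acceptor` labels, `da_distance_series`, `ha_distance_series`,
#'   `angle_series` (per frame), `occupancy` (percent), `mean_da` (mean
#'   donor-acceptor distance over satisfying frames, A) and `mean_energy`
#'   (kcal/mol). Use [hbond_table()] for a flat summary.
#' @export
detect_hbonds <- function(trj, criteria = hbond_criteria(),
                          occupancy_floor = 10) {
  stopifnot(inherits(trj, "trajectory"), inherits(criteria, "hbond_criteria"))
  top <- trj$topology
  a <- top$atoms
  hydrogens <- which(a$polar_hydrogen)
  acceptors <- which(a$acceptor)
  if (!length(hydrogens) || !length(acceptors))
    stop("topology annotates no donor hydrogens and/or no acceptors")

  in_p1 <- seq_len(nrow(a)) %in% top$partner1
  # candidate (donor, H, acceptor) with donor and acceptor on opposite partners
  cand <- do.call(rbind, lapply(hydrogens, function(h) {
    d <- a$bonded_heavy[h]
    acc <- acceptors[in_p1[acceptors] != in_p1[d]]
    if (!length(acc)) return(NULL)
    cbind(donor = d, hydrogen = h, acceptor = acc)
  }))
  if (is.null(cand)) return(list())

  nf <- n_frames(trj)
  records <- list()
  for (row in seq_len(nrow(cand))) {
    d <- cand[row, "donor"]; h <- cand[row, "hydrogen"]
    acc <- cand[row, "acceptor"]
    da <- ha <- ang <- numeric(nf)
    for (k in seq_len(nf)) {
      fr <- frame_coords(trj, k)
      da[k] <- sqrt(sum((fr[d, ] - fr[acc, ])^2))
      ha[k] <- sqrt(sum((fr[h, ] - fr[acc, ])^2))
      ang[k] <- .angle_deg(matrix(fr[d, ] - fr[h, ], 1),
                           matrix(fr[acc, ] - fr[h, ], 1))
    }
    sat <- da <= criteria$max_da_distance & ang >= criteria$min_dha_angle
    occupancy <- 100 * sum(sat) / nf
    if (occupancy < occupancy_floor) next
    records[[length(records) + 1L]] <- structure(list(
      donor = .atom_label(a, d), hydrogen = .atom_label(a, h),
      acceptor = .atom_label(a, acc),
      da_distance_series = da, ha_distance_series = ha, angle_series = ang,
      satisfied = sat, occupancy = occupancy,
      mean_da = mean(da[sat]),
      mean_energy = mean(hbond_energy(ha[sat]))),
      class = "hbond_record")
  }
  records
}

#' @export
print.hbond_record <- function(x, ...) {
  cat(sprintf("%s - %s ... %s: occupancy %.2f%%, <D..A> %.2f A, E %.2f kcal/mol\n",
              x$donor, x$hydrogen, x$acceptor, x$occupancy, x$mean_da,
              x$mean_energy))
  invisible(x)
}

#' Flat summary table of hydrogen-bond records
#'
#' @param records List of records from [detect_hbonds()].
#' @return A data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `mean_da`, `occupancy_pct`, `mean_energy`.
#' @export
hbond_table <- function(records) {
  if (!length(records))
    return(data.frame(donor = character(0), hydrogen = character(0),
                      acceptor = character(0), mean_da = numeric(0),
                      occupancy_pct = numeric(0), mean_energy = numeric(0)))
  do.call(rbind, lapply(records, function(r)
    data.frame(donor = r$donor, hydrogen = r$hydrogen, acceptor = r$acceptor,
               mean_da = r$mean_da, occupancy_pct = r$occupancy,
               mean_energy = r$mean_energy)))
}

#' Distance histogram and angle trace of a hydrogen bond
#'
#' @param record An `"hbond_record"` from [detect_hbonds()].
#' @param bin_width Histogram bin width for the hydrogen-acceptor distance,
#'   Angstrom (> 0).
#' @return A list with `distance_histogram` (data.frame `mid`, `frequency`;
#'   frequencies over all frames, summing to 1) and `angle_trace` (data.frame
#'   `frame`, `angle_deg` in frame order).
#' @export
geometry_profiles <- function(record, bin_width = 0.05) {
  stopifnot(inherits(record, "hbond_record"))
  if (bin_width <= 0) stop("bin_width must be > 0")
  ha <- record$ha_distance_series
  if (!length(ha)) stop("empty distance series")
  lo <- floor(min(ha) / bin_width) * bin_width
  breaks <- seq(lo, max(ha) + bin_width, by = bin_width)
  h <- hist(ha, breaks = breaks, plot = FALSE)
  list(distance_histogram = data.frame(mid = h$mids,
                                       frequency = h$counts / length(ha)),
       angle_trace = data.frame(frame = seq_along(record$angle_series),
                                angle_deg = record$angle_series))
}
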