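# Synthetic two-chain systems with known ground truth: coarse-grained dimers
# with designed inter-chain hydrogen bonds and salt bridges, a Metropolis
# Monte-Carlo sampler producing equilibrium-like snapshot ensembles around a
# reference pose, and parametric interaction-energy series for exercising the
# entropy estimator. Everything is reproducible from an explicit seed.

# run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards (no hidden global state leaks)
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a parametric interaction-energy series
#'
#' @param n_frames Number of frames (>= 2).
#' @param model `"gaussian"` (iid normal), `"two_state_mixture"` (two normal
#'   components separated by `mix_delta`, the second visited with probability
#'   `mix_weight`; `mean` is the overall mean), or `"ar1"` (stationary AR(1)
#'   with marginal sd `sigma` and lag-1 coefficient `ar1_coef`).
#' @param mean Series mean, kcal/mol.
#' @param sigma Fluctuation scale, kcal/mol (>= 0).
#' @param mix_weight,mix_delta Mixture parameters (weight in \[0, 1\]).
#' @param ar1_coef AR(1) coefficient in \[0, 1).
#' @param seed Integer seed.
#' @return An object of class `"series_spec"`.
#' @export
series_spec <- function(n_frames, model = c("gaussian", "two_state_mixture", "ar1"),
                        mean = 0, sigma = 1, mix_weight = 0.5, mix_delta = 1,
                        ar1_coef = 0.5, seed = 1) {
  if (!is.character(model) || !all(model %in% c("gaussian", "two_state_mixture", "ar1")))
    stop("model must be one of: gaussian, two_state_mixture, ar1")
  model <- match.arg(model)
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (sigma < 0) stop("sigma must be >= 0")
  if (mix_weight < 0 || mix_weight > 1) stop("mix_weight must lie in [0, 1]")
  if (ar1_coef < 0 || ar1_coef >= 1) stop("ar1_coef must lie in [0, 1)")
  structure(list(n_frames = as.integer(n_frames), model = model, mean = mean,
                 sigma = sigma, mix_weight = mix_weight, mix_delta = mix_delta,
                 ar1_coef = ar1_coef, seed = as.integer(seed)),
            class = "series_spec")
}

#' Generate a synthetic interaction-energy series
#'
#' Emulates approximately stationary fluctuations of an inter-partner
#' interaction energy, with controllable magnitude and correlation structure,
#' for exercising the interaction-entropy estimator against closed forms.
#'
#' @param spec A [series_spec()].
#' @param frame_interval Frame spacing, fs.
#' @param temperature Temperature tag for the series, K.
#' @return An [energy_series()] with `component = "total"`; identical output
#'   for identical seeds.
#' @export
gen_energy_series <- function(spec, frame_interval = 10, temperature = 300) {
  stopifnot(inherits(spec, "series_spec"))
  n <- spec$n_frames
  values <- .with_seed(spec$seed, {
    switch(spec$model,
      gaussian = stats::rnorm(n, spec$mean, spec$sigma),
      two_state_mixture = {
        state <- stats::rbinom(n, 1, spec$mix_weight)
        spec$mean + spec$mix_delta * (state - spec$mix_weight) +
          stats::rnorm(n, 0, spec$sigma)
      },
      ar1 = {
        phi <- spec$ar1_coef
        x <- numeric(n)
        x[1] <- stats::rnorm(1, 0, spec$sigma)
        innov <- stats::rnorm(n - 1, 0, spec$sigma * sqrt(1 - phi^2))
        for (t in 2:n) x[t] <- phi * x[t - 1] + innov[t - 1]
        spec$mean + x
      })
  })
  energy_series(values, component = "total", frame_interval = frame_interval,
                temperature = temperature)
}

#' Specification of a synthetic two-chain dimer
#'
#' @param n_residues_partner1,n_residues_partner2 Residue counts per chain
#'   (>= 1). Designed hydrogen bonds and salt bridges each claim one residue
#'   on both chains, so `n_designed_hbonds + n_salt_bridges` must not exceed
#'   either count.
#' @param n_designed_hbonds Inter-chain donor-H...acceptor triples posed to
#'   satisfy default hydrogen-bond criteria in the reference frame.
#' @param n_salt_bridges Opposite-charge (+1/-1 e) bead pairs within 4 A in
#'   the reference frame; each pair is net neutral.
#' @param tether_force_constant Harmonic tether force constant for sampling,
#'   kcal mol^-1 A^-2 (> 0).
#' @param seed Integer seed (controls small lateral placement jitter).
#' @return An object of class `"dimer_spec"`.
#' @export
dimer_spec <- function(n_residues_partner1 = 3, n_residues_partner2 = 3,
                       n_designed_hbonds = 1, n_salt_bridges = 1,
                       tether_force_constant = 10, seed = 1) {
  if (n_residues_partner1 < 1 || n_residues_partner2 < 1)
    stop("residue counts must be >= 1")
  if (n_designed_hbonds < 0 || n_salt_bridges < 0)
    stop("feature counts must be >= 0")
  needed <- n_designed_hbonds + n_salt_bridges
  if (needed > min(n_residues_partner1, n_residues_partner2))
    stop("n_designed_hbonds + n_salt_bridges (", needed,
         ") exceeds the residues available on a chain")
  if (tether_force_constant <= 0) stop("tether_force_constant must be > 0")
  structure(list(n_residues_partner1 = as.integer(n_residues_partner1),
                 n_residues_partner2 = as.integer(n_residues_partner2),
                 n_designed_hbonds = as.integer(n_designed_hbonds),
                 n_salt_bridges = as.integer(n_salt_bridges),
                 tether_force_constant = tether_force_constant,
                 seed = as.integer(seed)),
            class = "dimer_spec")
}

# per-bead Lennard-Jones parameters; only salt-bridge beads carry charge, so
# a dimer with no salt bridges has no close inter-chain charged pair by
# construction and designed hydrogen bonds are geometric features held by the
# tether, not by electrostatics
.bead_params <- data.frame(
  atom_name = c("CA", "N", "H", "O", "CB"),
  element = c("C", "N", "H", "O", "C"),
  rmin_half = c(1.9, 1.6, 0.5, 1.5, 2.0),
  epsilon = c(0.10, 0.10, 0.01, 0.10, 0.10),
  stringsAsFactors = FALSE)

#' Build a coarse-grained two-chain dimer with designed interface features
#'
#' Each residue carries 4-5 beads: a backbone bead (CA), a donor heavy atom
#' (N) with its polar hydrogen (H), an acceptor (O), and for salt-bridge
#' residues a charged bead (CB, +1 e on chain A, -1 e on chain B). The first
#' `n_designed_hbonds` residue pairs are posed so the chain-A N-H points at
#' the chain-B O with an H...A distance of 1.9 A, a donor-acceptor distance of
#' 2.9 A and a 180-degree angle; the next `n_salt_bridges` pairs place their
#' CB beads 3.5 A apart. All other polar groups face away from the interface.
#' The construction is verified against [detect_hbonds()] before returning.
#'
#' @param spec A [dimer_spec()].
#' @return A list with elements `topology` (a [topology()], chain A =
#'   partner1, chain B = partner2) and `reference` (the `n_atoms x 3`
#'   reference coordinate matrix). Deterministic given `spec$seed`.
#' @export
build_toy_dimer <- function(spec) {
  stopifnot(inherits(spec, "dimer_spec"))
  n1 <- spec$n_residues_partner1
  n2 <- spec$n_residues_partner2
  nhb <- spec$n_designed_hbonds
  nsb <- spec$n_salt_bridges
  gap <- 8  # A between the two backbone planes

  jit <- .with_seed(spec$seed, stats::runif(n1 + n2, -0.3, 0.3))

  rows <- list(); coords <- list()
  resname <- function(idx) {
    if (idx <= nhb) "HBD" else if (idx <= nhb + nsb) "CHG" else "GLY"
  }
  add_atom <- function(chain, resno, name, xyz, charge = 0) {
    p <- .bead_params[.bead_params$atom_name == name, ]
    rows[[length(rows) + 1L]] <<- data.frame(
      atom_name = name, element = p$element, residue_number = resno,
      residue_name = resname(resno), chain_id = chain,
      charge = charge, rmin_half = p$rmin_half, epsilon = p$epsilon,
      donor_heavy = name == "N", acceptor = name == "O",
      polar_hydrogen = name == "H", bonded_heavy = NA_integer_,
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
  }

  a_h_pos <- vector("list", n1)   # chain-A hydrogen positions (designed bonds)
  a_cb_pos <- vector("list", n1)  # chain-A charged-bead positions

  for (i in seq_len(n1)) {
    b <- c(6 * (i - 1), jit[i], 0)
    hb <- i <= nhb
    sb <- !hb && i <= nhb + nsb
    add_atom("A", i, "CA", b)
    if (hb) {
      add_atom("A", i, "N", b + c(0, 0, 1.0))
      add_atom("A", i, "H", b + c(0, 0, 2.0))
      a_h_pos[[i]] <- b + c(0, 0, 2.0)
    } else {
      add_atom("A", i, "N", b + c(0.8, 0, -0.6))
      add_atom("A", i, "H", b + c(0.8, 0, -1.6))
    }
    add_atom("A", i, "O", b + c(-0.8, 0, -1.0))
    if (sb) {
      add_atom("A", i, "CB", b + c(0, 2.2, 1.2), charge = 1)
      a_cb_pos[[i]] <- b + c(0, 2.2, 1.2)
    }
  }
  for (j in seq_len(n2)) {
    b <- c(6 * (j - 1), jit[n1 + j], gap)
    hb <- j <= nhb
    sb <- !hb && j <= nhb + nsb
    add_atom("B", j, "CA", b)
    add_atom("B", j, "N", b + c(0.8, 0, 0.6))
    add_atom("B", j, "H", b + c(0.8, 0, 1.6))
    if (hb) {
      # acceptor placed 1.9 A beyond the chain-A hydrogen, on the N-H axis
      add_atom("B", j, "O", a_h_pos[[j]] + c(0, 0, 1.9))
    } else {
      add_atom("B", j, "O", b + c(-0.8, 0, 1.0))
    }
    if (sb) add_atom("B", j, "CB", a_cb_pos[[j]] + c(0, 0, 3.5), charge = -1)
  }

  atoms <- do.call(rbind, rows)
  # wire each hydrogen to the donor heavy atom of its own residue
  for (k in which(atoms$polar_hydrogen)) {
    d <- which(atoms$chain_id == atoms$chain_id[k] &
                 atoms$residue_number == atoms$residue_number[k] &
                 atoms$donor_heavy)
    atoms$bonded_heavy[k] <- d
  }
  top <- topology(atoms, "A", "B", temperature = 300)
  reference <- do.call(rbind, coords)
  dimnames(reference) <- NULL

  # verify the designed geometry before handing it out
  frozen <- trajectory(top, reference)
  found <- detect_hbonds(frozen, hbond_criteria())
  if (length(found) != nhb)
    stop("designed-geometry placement failed: ", length(found),
         " hydrogen bonds detected in the reference frame, expected ", nhb)
  list(topology = top, reference = reference)
}

#' Sample a trajectory around a reference pose by Metropolis Monte Carlo
#'
#' Single-atom Gaussian displacement moves under the potential
#' `U = E_interchain(Coulomb + LJ) + 1/2 k |x - x_ref|^2` (one tether per
#' atom), accepted with probability `min(1, exp(-dU/KT))`. The step size is
#' auto-tuned during a short burn-in toward ~40% acceptance, then held fixed
#' for production; one frame is recorded every `sweeps_per_frame` sweeps.
#' This produces equilibrium-like snapshot ensembles (the observable pipeline
#' needs no dynamics), analogous to a tightly restrained simulation around a
#' native pose.
#'
#' @param top A [topology()].
#' @param reference `n_atoms x 3` reference coordinates (Angstrom).
#' @param n_frames Number of frames to record.
#' @param temperature Temperature, K.
#' @param step_size Initial per-coordinate proposal standard deviation, A.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param tether_force_constant Tether force constant k, kcal mol^-1 A^-2.
#' @param sweeps_per_frame Sweeps between recorded frames.
#' @param frame_interval Nominal frame spacing recorded on the trajectory, fs.
#' @return A [trajectory()]. The production acceptance rate is stored in
#'   attribute `"acceptance_rate"`; a rate outside \[0.05, 0.95\] triggers a
#'   warning-level log message, not an error.
#' @export
sample_trajectory <- function(top, reference, n_frames, temperature = 300,
                              step_size = 0.3, seed = 1,
                              tether_force_constant = 10,
                              sweeps_per_frame = 1, frame_interval = 10) {
  stopifnot(inherits(top, "topology"))
  reference <- as.matrix(reference)
  n <- nrow(top$atoms)
  if (!all(dim(reference) == c(n, 3)))
    stop("reference does not match topology atom count")
  kt <- .kB * max(temperature, 1e-12)
  k_tether <- tether_force_constant
  a <- top$atoms
  in_p1 <- seq_len(n) %in% top$partner1

  # per-atom interaction tables against the opposite partner
  other_idx <- vector("list", n)
  qprod <- rmin <- epsv <- vector("list", n)
  active <- logical(n)
  for (i in seq_len(n)) {
    o <- if (in_p1[i]) top$partner2 else top$partner1
    other_idx[[i]] <- o
    qprod[[i]] <- .kCoulomb * a$charge[i] * a$charge[o]
    rmin[[i]] <- a$rmin_half[i] + a$rmin_half[o]
    epsv[[i]] <- sqrt(a$epsilon[i] * a$epsilon[o])
    active[i] <- any(qprod[[i]] != 0) || any(epsv[[i]] != 0)
  }
  atom_energy <- function(i, xi, X) {
    o <- other_idx[[i]]
    dx <- X[o, 1] - xi[1]; dy <- X[o, 2] - xi[2]; dz <- X[o, 3] - xi[3]
    r2 <- dx * dx + dy * dy + dz * dz
    if (any(r2 == 0)) return(Inf)
    r <- sqrt(r2)
    sr6 <- (rmin[[i]] / r)^6
    sum(qprod[[i]] / r) + sum(epsv[[i]] * (sr6 * sr6 - 2 * sr6))
  }

  coords <- array(NA_real_, dim = c(n, 3, n_frames))
  acc_rate <- NA_real_
  .with_seed(seed, {
    X <- reference
    step <- step_size
    # burn-in with crude step adaptation toward ~40% acceptance
    for (round in 1:15) {
      acc <- 0L; tot <- 0L
      for (sweep in 1:4) {
        for (i in seq_len(n)) {
          prop <- X[i, ] + stats::rnorm(3, 0, step)
          dU <- 0.5 * k_tether * (sum((prop - reference[i, ])^2) -
                                    sum((X[i, ] - reference[i, ])^2))
          if (active[i])
            dU <- dU + atom_energy(i, prop, X) - atom_energy(i, X[i, ], X)
          tot <- tot + 1L
          if (is.finite(dU) && (dU <= 0 || stats::runif(1) < exp(-dU / kt))) {
            X[i, ] <- prop; acc <- acc + 1L
          }
        }
      }
      rate <- acc / tot
      if (rate < 0.3) step <- step / 1.6
      else if (rate > 0.5) step <- step * 1.4
    }
    # production at fixed step size (preserves detailed balance)
    acc <- 0L; tot <- 0L
    for (f in seq_len(n_frames)) {
      for (sweep in seq_len(sweeps_per_frame)) {
        for (i in seq_len(n)) {
          prop <- X[i, ] + stats::rnorm(3, 0, step)
          dU <- 0.5 * k_tether * (sum((prop - reference[i, ])^2) -
                                    sum((X[i, ] - reference[i, ])^2))
          if (active[i])
            dU <- dU + atom_energy(i, prop, X) - atom_energy(i, X[i, ], X)
          tot <- tot + 1L
          if (is.finite(dU) && (dU <= 0 || stats::runif(1) < exp(-dU / kt))) {
            X[i, ] <- prop; acc <- acc + 1L
          }
        }
      }
      coords[, , f] <- X
    }
    acc_rate <- acc / tot
  })
  if (acc_rate < 0.05 || acc_rate > 0.95)
    message(sprintf(
      "sampler log: production acceptance rate %.3f outside [0.05, 0.95]",
      acc_rate))
  trj <- trajectory(top, coords, frame_interval = frame_interval)
  attr(trj, "acceptance_rate") <- acc_rate
  trj
}
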