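test_that("pair_energy matches hand-evaluated Coulomb and LJ values", {
  # unit charges at r chosen so 332.0637*(-1)/r = -100 exactly
  a <- list(charge = 1, rmin_half = 0, epsilon = 0)
  b <- list(charge = -1, rmin_half = 0, epsilon = 0)
  expect_equal(pair_energy(a, b, 3.320637)$ele, -100)

  # LJ minimum: r = R_min,ij gives exactly -eps_ij
  a <- list(charge = 0, rmin_half = 1.75, epsilon = 0.4)
  b <- list(charge = 0, rmin_half = 1.75, epsilon = 0.1)
  expect_equal(pair_energy(a, b, 3.5)$vdw, -sqrt(0.4 * 0.1))

  # off-minimum hand evaluation: eps_ij = 0.1, Rmin = 3.5, r = 3
  a <- list(charge = 0, rmin_half = 1.75, epsilon = 0.1)
  b <- list(charge = 0, rmin_half = 1.75, epsilon = 0.1)
  expect_equal(pair_energy(a, b, 3)$vdw,
               0.1 * ((3.5 / 3)^12 - 2 * (3.5 / 3)^6), tolerance = 1e-12)
  expect_equal(pair_energy(a, b, 3)$vdw, 0.1315, tolerance = 1e-3)

  expect_error(pair_energy(a, b, 0), "> 0")
})

test_that("group_interaction_energy equals the brute-force pair sum", {
  # 2 atoms in partner1, 1 in partner2: exactly two inter-partner terms
  top <- make_point_topology(charge = c(0.5, -0.3, 0.8),
                             chain = c("A", "A", "B"),
                             rmin_half = c(1.5, 1.7, 1.6),
                             epsilon = c(0.1, 0.2, 0.15))
  fr <- rbind(c(0, 0, 0), c(1.2, 0.5, 0), c(3.1, 0.2, 1.0))
  at <- function(i) as.list(top$atoms[i, ])
  r13 <- sqrt(sum((fr[1, ] - fr[3, ])^2))
  r23 <- sqrt(sum((fr[2, ] - fr[3, ])^2))
  hand_ele <- pair_energy(at(1), at(3), r13)$ele + pair_energy(at(2), at(3), r23)$ele
  hand_vdw <- pair_energy(at(1), at(3), r13)$vdw + pair_energy(at(2), at(3), r23)$vdw
  got <- group_interaction_energy(fr, top)
  expect_equal(got$ele, hand_ele, tolerance = 1e-12)
  expect_equal(got$vdw, hand_vdw, tolerance = 1e-12)
  expect_identical(got$total, got$ele + got$vdw)

  # all charges and epsilons zero -> exactly (0, 0, 0)
  top0 <- make_point_topology(charge = c(0, 0, 0), chain = c("A", "A", "B"))
  expect_identical(group_interaction_energy(fr, top0)$total, 0)

  # coincident inter-partner atoms are an error naming the pair
  fr2 <- fr; fr2[3, ] <- fr2[1, ]
  expect_error(group_interaction_energy(fr2, top), "coincident")
})

test_that("inter-partner energy is invariant to rigid translation and partner swap", {
  set.seed(1)
  top <- make_point_topology(charge = runif(6, -1, 1),
                             chain = rep(c("A", "B"), each = 3),
                             rmin_half = runif(6, 1, 2),
                             epsilon = runif(6, 0.05, 0.3))
  fr <- matrix(runif(18, 0, 5), ncol = 3)
  fr[4:6, 3] <- fr[4:6, 3] + 6  # keep partners apart
  e1 <- group_interaction_energy(fr, top)
  e2 <- group_interaction_energy(sweep(fr, 2, c(13.7, -2.1, 8.9), "+"), top)
  expect_equal(e1$total, e2$total, tolerance = 1e-10)

  swapped <- topology(top$atoms, "B", "A", temperature = 300)
  e3 <- group_interaction_energy(fr, swapped)
  expect_equal(e3$ele, e1$ele, tolerance = 1e-12)
  expect_equal(e3$vdw, e1$vdw, tolerance = 1e-12)
})

test_that("scaling all charges by c scales ele by c^2 and leaves vdw fixed", {
  set.seed(2)
  atoms <- make_point_topology(charge = runif(6, -1, 1),
                               chain = rep(c("A", "B"), each = 3),
                               rmin_half = 1.5, epsilon = 0.1)$atoms
  fr <- matrix(runif(18, 0, 4), ncol = 3)
  fr[4:6, 1] <- fr[4:6, 1] + 5
  base <- group_interaction_energy(fr, topology(atoms, "A", "B"))
  for (c_scale in c(0.5, 2, 3)) {
    atoms2 <- atoms; atoms2$charge <- atoms$charge * c_scale
    e <- group_interaction_energy(fr, topology(atoms2, "A", "B"))
    expect_equal(e$ele, c_scale^2 * base$ele, tolerance = 1e-10)
    expect_equal(e$vdw, base$vdw, tolerance = 1e-12)
  }
})

test_that("interaction_energy_series is per-frame self-consistent", {
  d <- toy_dimer()
  trj <- sample_trajectory(d$topology, d$reference, n_frames = 10, seed = 5)
  gas <- interaction_energy_series(trj)
  expect_length(gas$total$values, 10)
  single <- group_interaction_energy(frame_coords(trj, 7), trj$topology)
  expect_equal(gas$total$values[7], single$total, tolerance = 1e-12)
  expect_equal(gas$ele$values + gas$vdw$values, gas$total$values)

  # frozen trajectory -> constant series; 1-frame trajectory -> length 1
  frozen <- trajectory(d$topology, array(rep(d$reference, 3),
                                         dim = c(nrow(d$reference), 3, 3)))
  gfro <- interaction_energy_series(frozen)
  expect_equal(diff(range(gfro$total$values)), 0)
  one <- interaction_energy_series(trajectory(d$topology, d$reference))
  expect_length(one$total$values, 1)
  expect_equal(one$total$values,
               group_interaction_energy(d$reference, d$topology)$total)
})

test_that("per-residue decomposition conserves the frame totals", {
  set.seed(3)
  top <- make_point_topology(charge = runif(8, -1, 1),
                             chain = rep(c("A", "B"), each = 4),
                             rmin_half = runif(8, 1, 2),
                             epsilon = runif(8, 0.01, 0.3),
                             residue_number = c(1, 1, 2, 2, 1, 1, 2, 2))
  coords <- array(runif(8 * 3 * 4, 0, 6), dim = c(8, 3, 4))
  coords[5:8, 3, ] <- coords[5:8, 3, ] + 7
  trj <- trajectory(top, coords)
  gas <- interaction_energy_series(trj)
  for (side in c("partner1", "partner2")) {
    res <- per_residue_interaction_series(trj, side)
    expect_length(res, 2)
    tot <- Reduce(`+`, lapply(res, function(r) r$total$values))
    expect_lt(max(abs(tot - gas$total$values)), 1e-8)
  }
})

test_that("degenerate residue selections behave as documented", {
  d <- toy_dimer(n_hb = 1, n_sb = 0, n_res = 1)  # single residue per partner
  trj <- sample_trajectory(d$topology, d$reference, n_frames = 5, seed = 9)
  gas <- interaction_energy_series(trj)
  res <- per_residue_interaction_series(trj, "partner1")
  expect_length(res, 1)
  expect_equal(res[[1]]$total$values, gas$total$values, tolerance = 1e-12)

  # residue with all-zero charges and epsilons contributes a zero series
  top <- make_point_topology(charge = c(1, 0, -1), chain = c("A", "A", "B"),
                             rmin_half = c(1, 0, 1), epsilon = c(0.1, 0, 0.1),
                             residue_number = c(1, 2, 1))
  trj2 <- trajectory(top, rbind(c(0, 0, 0), c(2, 0, 0), c(0, 0, 4)))
  res2 <- per_residue_interaction_series(trj2, "partner1")
  expect_identical(res2[["A:2:RES"]]$total$values, 0)
})
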