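test_that("Shrake-Rupley SASA matches sphere closed forms", {
  # isolated sphere: fully accessible, 4*pi*(r+probe)^2
  a1 <- shrake_rupley_sasa(matrix(0, 1, 3), radii = 1.6)
  expect_equal(a1, 4 * pi * 3^2, tolerance = 1e-12)
  expect_equal(a1, 113.097, tolerance = 1e-3)

  # two atoms far apart: no occlusion, areas add
  fr2 <- rbind(c(0, 0, 0), c(100, 0, 0))
  a2 <- shrake_rupley_sasa(fr2, radii = c(1.6, 2.0))
  expect_equal(a2, 4 * pi * c(3^2, 3.4^2), tolerance = 1e-12)

  # two equal spheres (solvent radius 3) at distance 3: each loses a cap of
  # area 2*pi*R*h with h = R - d/2; analytic total 2*(4*pi*9 - 9*pi)
  fr3 <- rbind(c(0, 0, 0), c(3, 0, 0))
  a3 <- sum(shrake_rupley_sasa(fr3, radii = 1.6, probe = 1.4, n_points = 960))
  analytic <- 2 * (4 * pi * 9 - 2 * pi * 3 * 1.5)
  expect_equal(a3, analytic, tolerance = 0.02)

  expect_error(shrake_rupley_sasa(matrix(0, 1, 3), 1.6, n_points = 8), "16")
  expect_error(shrake_rupley_sasa(matrix(0, 1, 3), -1), "> 0")
})

test_that("SASA shrinks monotonically as a neighbour approaches", {
  areas <- vapply(c(20, 6, 4, 3, 2.5), function(dist)
    shrake_rupley_sasa(rbind(c(0, 0, 0), c(dist, 0, 0)), radii = 1.6)[1],
    numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("the nonpolar term is the literal linear SASA model", {
  expect_identical(nonpolar_term(0), 0.92)
  expect_equal(nonpolar_term(1000), 0.00542 * 1000 + 0.92)
  expect_equal(nonpolar_term(1000), 6.34, tolerance = 1e-12)
  expect_error(nonpolar_term(-1), ">= 0")
  # binding form: the per-species offsets do not cancel
  expect_equal(nonpolar_term(100) - nonpolar_term(60) - nonpolar_term(40),
               -0.92, tolerance = 1e-12)
})

test_that("GB reduces to the Born ion and to a hand-evaluated double sum", {
  # a topology needs both partners; the far second bead is uncharged
  ion2 <- make_point_topology(charge = c(1, 0), chain = c("A", "B"))
  born <- gb_polar(matrix(c(0, 0, 0, 50, 0, 0), 2, 3, byrow = TRUE), ion2,
                   selection = 1, intrinsic_radii = 2)
  expect_equal(born, -0.5 * 332.0637 * (1 - 1 / 80) / 2, tolerance = 1e-10)
  expect_equal(born, -81.978, tolerance = 1e-3)

  # all charges zero -> 0
  top0 <- make_point_topology(charge = c(0, 0), chain = c("A", "B"))
  expect_identical(gb_polar(rbind(c(0, 0, 0), c(3, 0, 0)), top0), 0)

  # two-atom symmetric system vs direct evaluation of the descreening
  # integral and the Still double sum, written out independently here
  q <- c(0.7, 0.7); rho <- c(1.5, 1.5); sc <- 0.72; r <- 4
  s <- sc * rho[2]
  L <- max(abs(r - s), rho[1]); U <- r + s
  I <- 0.5 * (1 / L - 1 / U + (r / 4) * (1 / U^2 - 1 / L^2) +
                (1 / (2 * r)) * log(L / U) +
                (s^2 / (4 * r)) * (1 / L^2 - 1 / U^2))
  a_eff <- 1 / (1 / rho[1] - I)
  f_off <- sqrt(r^2 + a_eff^2 * exp(-r^2 / (4 * a_eff^2)))
  dbl <- q[1]^2 / a_eff + q[2]^2 / a_eff + 2 * q[1] * q[2] / f_off
  hand <- -0.5 * 332.0637 * (1 - 1 / 80) * dbl
  top2 <- make_point_topology(charge = q, chain = c("A", "B"), element = "C")
  got <- gb_polar(rbind(c(0, 0, 0), c(r, 0, 0)), top2,
                  intrinsic_radii = rho)
  expect_equal(got, hand, tolerance = 1e-8)
})

test_that("GB approaches the Born-ion sum at infinite separation and is rigid-motion invariant", {
  q <- c(0.5, -0.8); rho <- c(1.4, 1.7)
  top <- make_point_topology(charge = q, chain = c("A", "B"))
  far <- gb_polar(rbind(c(0, 0, 0), c(1e7, 0, 0)), top, intrinsic_radii = rho)
  born_sum <- -0.5 * 332.0637 * (1 - 1 / 80) * sum(q^2 / rho)
  expect_equal(far, born_sum, tolerance = 1e-6)

  # rigid rotation + translation leaves the energy unchanged
  fr <- rbind(c(0, 0, 0), c(3.5, 1.2, -0.7))
  th <- 0.83
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  fr_mov <- sweep(fr %*% rot, 2, c(12, -5, 3), "+")
  expect_equal(gb_polar(fr, top, intrinsic_radii = rho),
               gb_polar(fr_mov, top, intrinsic_radii = rho),
               tolerance = 1e-10)
})

test_that("binding_solvation follows the single-trajectory protocol", {
  # uncharged dimer with partners far apart: dG_pol = 0 and dG_np = -0.92
  # (the nonpolar offsets do not cancel; dSASA = 0 with no occlusion)
  top <- make_point_topology(charge = c(0, 0), chain = c("A", "B"),
                             element = "C")
  ref <- rbind(c(0, 0, 0), c(60, 0, 0))
  trj <- trajectory(top, array(rep(ref, 3), dim = c(2, 3, 3)))
  bs <- binding_solvation(trj, n_points = 240)
  expect_equal(bs$dg_pol, 0)
  expect_equal(bs$dg_np, -0.92, tolerance = 1e-10)
  expect_equal(bs$dg_sol, bs$dg_pol + bs$dg_np)
  # frozen frames give identical per-frame values
  expect_equal(diff(range(bs$frames$dg_np)), 0)
  # offset-cancelling convention zeroes dG_np here
  bs0 <- binding_solvation(trj, n_points = 240, drop_np_offset = TRUE)
  expect_equal(bs0$dg_np, 0, tolerance = 1e-10)

  # external polar series passes through untouched
  ext <- binding_solvation(trj, stride = 2,
                           polar_source = "external_file",
                           external_polar = c(-5, -5), n_points = 240)
  expect_equal(ext$dg_pol, -5)
  expect_error(binding_solvation(trj, polar_source = "external_file",
                                 external_polar = c(-5, -5), n_points = 240),
               "3 selected frames")

  # external CSV path with complex/p1/p2 columns
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,complex,p1,p2", "1,-10,-3,-2", "2,-12,-4,-2",
               "3,-11,-3,-3"), p)
  extf <- binding_solvation(trj, polar_source = "external_file",
                            external_polar = p, n_points = 240)
  expect_equal(extf$frames$dg_pol, c(-5, -6, -5))
})
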