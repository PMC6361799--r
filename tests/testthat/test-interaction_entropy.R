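test_that("the estimator matches hand and closed-form oracles", {
  # constant series: no fluctuation, -TdS = 0
  expect_identical(interaction_entropy(rep(-50, 100), 300)$minus_t_delta_s, 0)

  # two points {-10, -12} at 300 K: dE = +/-1, so
  # -TdS = KT * ln cosh(beta * 1) -- hand-evaluated
  ie2 <- interaction_entropy(energy_series(c(-10, -12)), 300)
  expect_equal(ie2$minus_t_delta_s, kT300 * log(cosh(1 / kT300)),
               tolerance = 1e-12)
  expect_equal(ie2$minus_t_delta_s, 0.6072, tolerance = 1e-4)
  expect_equal(ie2$mean_interaction, -11)
  expect_equal(ie2$beta * kT300, 1, tolerance = 1e-12)

  # Gaussian fluctuations: -TdS -> sigma^2 / (2KT)
  s <- gen_energy_series(series_spec(1e6, "gaussian", mean = -100,
                                     sigma = 0.5, seed = 123))
  got <- interaction_entropy(s)$minus_t_delta_s
  expect_equal(got, 0.5^2 / (2 * kT300), tolerance = 0.02)
  expect_equal(0.5^2 / (2 * kT300), 0.2097, tolerance = 1e-3)

  # single frame returns 0; bad inputs error
  expect_identical(interaction_entropy(-3.2, 300)$minus_t_delta_s, 0)
  expect_error(interaction_entropy(c(1, NaN), 300), "non-finite")
  expect_error(interaction_entropy(c(1, 2), -1), "temperature")
})

test_that("-TdS is non-negative and shift-invariant on random series", {
  set.seed(99)
  for (i in 1:100) {
    x <- switch(1 + i %% 3,
                rnorm(50, sd = runif(1, 0.01, 2)),
                rcauchy(30) * 0.1,
                runif(40, -5, 5))
    v <- interaction_entropy(x, 300)$minus_t_delta_s
    expect_gte(v, 0)
    v_shift <- interaction_entropy(x + 1234.5, 300)$minus_t_delta_s
    expect_lt(abs(v - v_shift), 1e-10)
  }
})

test_that("log-sum-exp evaluation agrees with the naive average and survives overflow", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(200, sd = 0.3)  # small enough that naive exp does not overflow
    kt <- kT300
    naive <- kt * log(mean(exp((x - mean(x)) / kt)))
    stable <- interaction_entropy(x, 300)$minus_t_delta_s
    expect_equal(stable, naive, tolerance = 1e-10)
  }
  # beta * dE ~ 750: naive exp overflows doubles, the estimator must not
  x_big <- c(rep(0, 999), 751 * kT300)
  expect_true(is.finite(interaction_entropy(x_big, 300)$minus_t_delta_s))
  expect_false(is.finite(log(mean(exp((x_big - mean(x_big)) / kT300)))))
})

test_that("the Gaussian-limit error shrinks with sample size", {
  # relative error vs sigma^2/(2KT), averaged over 20 seeds, should fall
  # monotonically as n grows through 1e4, 1e5, 1e6 (beta * sigma < 1 regime)
  sigma <- 0.3
  truth <- sigma^2 / (2 * kT300)
  mean_err <- vapply(c(1e4, 1e5, 1e6), function(n) {
    errs <- vapply(1:20, function(seed) {
      s <- gen_energy_series(series_spec(n, "gaussian", sigma = sigma,
                                         seed = seed))
      abs(interaction_entropy(s)$minus_t_delta_s - truth) / truth
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) < 0))
})

test_that("convergence traces are standalone prefix estimates", {
  s <- gen_energy_series(series_spec(500, "ar1", mean = -20, sigma = 1,
                                     ar1_coef = 0.6, seed = 4))
  tr <- convergence_trace(s, stride = 50)
  # final point equals the full-series estimate bit-for-bit
  expect_identical(tr$minus_t_delta_s[nrow(tr)],
                   interaction_entropy(s)$minus_t_delta_s)
  # an interior point equals the estimate recomputed on that prefix alone
  m <- tr$frame[3]
  standalone <- interaction_entropy(s$values[seq_len(m)], 300)$minus_t_delta_s
  expect_identical(tr$minus_t_delta_s[3], standalone)

  # constant series -> all-zero trace; invalid stride errors
  tr0 <- convergence_trace(rep(5, 100), 300, stride = 10)
  expect_true(all(tr0$minus_t_delta_s == 0))
  expect_error(convergence_trace(s, stride = 501), "stride")
  expect_error(convergence_trace(s, stride = 0), "stride")

  # ie_result carries the same trace contract
  ie <- interaction_entropy(s)
  expect_identical(ie$convergence_trace$minus_t_delta_s[
    nrow(ie$convergence_trace)], ie$minus_t_delta_s)
})

test_that("per-residue entropy applies the estimator residue-wise", {
  # constant residue series -> 0
  res <- list(r1 = list(total = energy_series(rep(2, 50))),
              r2 = list(total = energy_series(rnorm(50))))
  pr <- per_residue_entropy(res, 300)
  expect_identical(unname(pr["r1"]), 0)
  expect_gt(pr["r2"], 0)

  # single-residue partner: per-residue value equals the whole-system IE
  d <- toy_dimer(n_hb = 1, n_sb = 0, n_res = 1)
  trj <- sample_trajectory(d$topology, d$reference, n_frames = 50, seed = 13)
  gas <- interaction_energy_series(trj)
  rs <- per_residue_interaction_series(trj, "partner2")
  expect_equal(unname(per_residue_entropy(rs)),
               interaction_entropy(gas$total)$minus_t_delta_s,
               tolerance = 1e-10)

  # independent gaussian residues each recover sigma_r^2/(2KT)
  sig <- c(0.2, 0.4)
  res_g <- lapply(1:2, function(k)
    list(total = gen_energy_series(series_spec(2e5, "gaussian",
                                               sigma = sig[k], seed = 40 + k))))
  names(res_g) <- c("a", "b")
  prg <- per_residue_entropy(res_g, 300)
  expect_equal(unname(prg), sig^2 / (2 * kT300), tolerance = 0.05)

  # mismatched lengths are an error
  res_bad <- list(a = list(total = energy_series(1:5)),
                  b = list(total = energy_series(1:6)))
  expect_error(per_residue_entropy(res_bad, 300), "length")
})

test_that("block uncertainty follows the sample-sd definition", {
  # identical blocks -> 0
  expect_equal(block_uncertainty(rep(c(1, 2), 20), 300, n_blocks = 10), 0)

  # blocks with means {1,2,3}: sample sd (n-1 denominator) is exactly 1
  x <- c(rep(1, 4), rep(2, 4), rep(3, 4))
  expect_identical(block_uncertainty(x, 300, n_blocks = 3, statistic = "mean"), 1)

  # fixed-seed series reproduces its value
  s <- gen_energy_series(series_spec(400, "gaussian", sigma = 1, seed = 6))
  expect_identical(block_uncertainty(s), block_uncertainty(s))
  expect_error(block_uncertainty(1:5, 300, n_blocks = 10), "too short")
  expect_error(block_uncertainty(1:50, 300, n_blocks = 1), "n_blocks")
})
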