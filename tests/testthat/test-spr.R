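test_that("apparent K follows the two-state closed form", {
  # ka1/kd1 = 1e8 1/M and ka2/kd2 = 1: K = 2e8, K_D = 5e-9 M
  p <- two_state_params(ka1 = 1e5, kd1 = 1e-3, ka2 = 1e-3, kd2 = 1e-3)
  kk <- apparent_K(p)
  expect_equal(kk$K, 2e8)
  expect_equal(kk$K_D, 5e-9)

  # ka2 = 0 reduces exactly to the 1:1 Langmuir affinity
  p0 <- two_state_params(ka1 = 2e5, kd1 = 4e-3, ka2 = 0, kd2 = 1e-2)
  expect_equal(apparent_K(p0)$K, 2e5 / 4e-3)

  # linear in ka1
  p2 <- two_state_params(ka1 = 2e5, kd1 = 1e-3, ka2 = 1e-3, kd2 = 1e-3)
  p1 <- two_state_params(ka1 = 1e5, kd1 = 1e-3, ka2 = 1e-3, kd2 = 1e-3)
  expect_equal(apparent_K(p2)$K / apparent_K(p1)$K, 2)

  expect_error(apparent_K(two_state_params(1e5, 0, 1e-3, 1e-3)), "positive")
})

test_that("simulated sensorgrams satisfy the model's physical limits", {
  p <- two_state_params(ka1 = 1e5, kd1 = 5e-3, ka2 = 2e-3, kd2 = 1e-3,
                        Rmax = 120)

  # zero analyte: flat zero trace
  flat <- simulate_two_state(p, conc = 0, t_assoc = 60, t_dissoc = 60)
  expect_true(all(abs(flat$response) < 1e-9))

  tr <- simulate_two_state(p, conc = 133e-9, t_assoc = 300, t_dissoc = 120)
  expect_equal(tr$response[1], 0, tolerance = 1e-9)
  expect_true(all(tr$response <= p$Rmax + 1e-9))       # mass conservation
  expect_true(all(tr$response >= -1e-9))

  # ka2 = 0, long association: Langmuir equilibrium Rmax C / (C + KD1)
  p1 <- two_state_params(ka1 = 1e5, kd1 = 1e-2, ka2 = 0, kd2 = 1e-2,
                         Rmax = 100)
  C <- 266e-9
  eq <- simulate_two_state(p1, C, t_assoc = 5000, t_dissoc = 10)
  r_assoc <- eq$response[eq$phase == "association"]
  expect_equal(tail(r_assoc, 1), 100 * C / (C + 1e-2 / 1e5),
               tolerance = 1e-3)
})

test_that("closed-form trajectory matches an independent ODE integration", {
  skip_if_not_installed("deSolve")
  p <- two_state_params(ka1 = 3e5, kd1 = 2e-3, ka2 = 5e-3, kd2 = 1.5e-3,
                        Rmax = 90)
  C <- 66e-9
  rhs <- function(t, y, parms) {
    AL <- y[1]; ALs <- y[2]
    dAL <- p$ka1 * parms$C * (p$Rmax - AL - ALs) - p$kd1 * AL -
      p$ka2 * AL + p$kd2 * ALs
    dALs <- p$ka2 * AL - p$kd2 * ALs
    list(c(dAL, dALs))
  }
  times <- seq(0, 180, by = 1)
  ode_a <- deSolve::lsoda(c(0, 0), times, rhs, parms = list(C = C),
                          rtol = 1e-10, atol = 1e-12)
  tr <- simulate_two_state(p, C, t_assoc = 180, t_dissoc = 120, step = 1)
  r_assoc <- tr$response[tr$phase == "association"]
  expect_equal(r_assoc, ode_a[, 2] + ode_a[, 3], tolerance = 1e-6)

  ode_d <- deSolve::lsoda(ode_a[nrow(ode_a), 2:3], seq(0, 120, 1), rhs,
                          parms = list(C = 0), rtol = 1e-10, atol = 1e-12)
  r_dis <- tr$response[tr$phase == "dissociation"]
  expect_equal(r_dis, (ode_d[, 2] + ode_d[, 3])[-1], tolerance = 1e-6)
})

test_that("two-state fitting round-trips noise-free series within 1%", {
  p <- two_state_params(ka1 = 2e5, kd1 = 8e-3, ka2 = 4e-3, kd2 = 2e-3,
                        Rmax = 100)
  sg <- generate_sensorgrams(p, t_assoc = 120, t_dissoc = 120, step = 2)
  fit <- fit_two_state(sg)
  expect_true(fit$converged)
  truth <- apparent_K(p)
  expect_equal(fit$K_D / truth$K_D, 1, tolerance = 0.01)

  # rescaling every trace's response rescales Rmax only, K_D unchanged
  sg2 <- sg
  sg2$response <- sg2$response * 3
  fit2 <- fit_two_state(sg2)
  expect_equal(fit2$K_D / truth$K_D, 1, tolerance = 0.01)

  # per-concentration mode averages apparent K over traces
  fit_pc <- fit_two_state(sg, mode = "per_conc")
  expect_equal(fit_pc$K_D / truth$K_D, 1, tolerance = 0.05)
  expect_length(fit_pc$K_values, 6)

  expect_error(fit_two_state(sg[sg$conc > 2e-7, ]), ">= 3")
})

test_that("two-state K_D recovery tolerates measurement noise", {
  p <- two_state_params(ka1 = 2e5, kd1 = 8e-3, ka2 = 4e-3, kd2 = 2e-3,
                        Rmax = 100)
  truth <- apparent_K(p)$K_D
  err <- vapply(1:6, function(s) {
    sg <- generate_sensorgrams(p, t_assoc = 120, t_dissoc = 120, step = 2,
                               noise_sd = 2, seed = 100 + s)
    abs(log10(fit_two_state(sg)$K_D / truth))
  }, numeric(1))
  expect_lt(stats::median(err), 0.1)
})

test_that("IC50 sigmoid fit recovers the inflection and flags failures", {
  lev <- c(0.1, 0.5, 1, 2, 5, 10, 20)   # percent plasma
  sig <- fourpl(lev, a = 100, b = 1.4, c = 5, d = 2)
  ic <- fit_ic50(lev, sig)
  expect_equal(ic$ic50, 5, tolerance = 1e-6)
  expect_false(ic$extrapolated)
  expect_false(ic$no_inhibition)

  # zero competitor level is dropped before the log-axis fit
  ic0 <- fit_ic50(c(0, lev), c(100, sig))
  expect_equal(ic0$n_dropped, 1)
  expect_equal(ic0$ic50, 5, tolerance = 1e-4)

  # rising signal: no inhibition
  up <- fit_ic50(lev, fourpl(lev, a = 5, b = 1, c = 5, d = 100))
  expect_true(up$no_inhibition)

  # noisy recovery: median within 10% over 50 seeds
  rec <- vapply(1:50, function(s) {
    set.seed(s)
    noisy <- sig * exp(stats::rnorm(length(sig), 0, 0.05))
    fit_ic50(lev, noisy)$ic50
  }, numeric(1))
  expect_lt(abs(stats::median(rec) / 5 - 1), 0.10)
})

test_that("seeded sensorgram noise is reproducible and seed-sensitive", {
  p <- two_state_params(1e5, 5e-3, 2e-3, 1e-3, 80)
  a <- simulate_two_state(p, 1e-7, 60, 60, noise_sd = 1, seed = 4)
  b <- simulate_two_state(p, 1e-7, 60, 60, noise_sd = 1, seed = 4)
  c2 <- simulate_two_state(p, 1e-7, 60, 60, noise_sd = 1, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$response, c2$response))
})
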