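test_that("compartment mass-balance right-hand side matches hand substitution", {
  k0 <- kinetic_params(k01 = 0, k10 = 0, k12 = 0, k21 = 0,
                       k13_young = 0, k13_mature = 0)
  z <- compartment_rhs(0, compartment_state(), k0, k13 = 0)
  expect_equal(unname(unlist(z)), c(0, 0, 0, 0))

  # sorption equilibrium: k12 Sl = k21 Ss gives dSs = 0
  k <- kinetic_params(k01 = 0, k10 = 0, k12 = 0.02, k21 = 0.04)
  eq <- compartment_rhs(0, compartment_state(Sl = 2, Ss = 1), k, k13 = 0)
  expect_equal(eq$dSs[1, 1], 0)

  # direct substitution
  k <- kinetic_params(k01 = 0.1, k10 = 0, k12 = 0.02, k21 = 0)
  r <- compartment_rhs(1, compartment_state(Sl = 2, Ss = 0), k, k13 = 0.03)
  expect_equal(r$dSl[1, 1], 0.1 - (0.02 + 0.03) * 2) # = 0
  expect_equal(r$dSs[1, 1], 0.04)
  expect_equal(r$dPl[1, 1], 0.06)
  expect_equal(r$water_exchange[1, 1], -0.1)
})

test_that("closed form reduces to the scalar solution when only uptake is active", {
  k01 <- 0.05; k13 <- 0.003; cc <- 2
  k <- kinetic_params(k01 = k01, k10 = 0, k12 = 0, k21 = 0, k13_young = k13)
  for (t in c(0, 10, 100, 2000)) {
    s <- analytic_compartments(k, cc, t)
    Sl_exact <- k01 * cc / k13 * (1 - exp(-k13 * t))
    expect_equal(s$Sl[1, 1], Sl_exact, tolerance = 1e-12)
    expect_equal(s$Pl[1, 1], k01 * cc * t - Sl_exact, tolerance = 1e-12)
    expect_equal(s$Ss[1, 1], 0)
  }
  # t = 0 returns the initial state
  init <- compartment_state(Sl = 1, Ss = 2, Pl = 3)
  s0 <- analytic_compartments(kinetic_params(), 5, 0, init)
  expect_equal(s0$Sl[1, 1], 1); expect_equal(s0$Ss[1, 1], 2); expect_equal(s0$Pl[1, 1], 3)
})

test_that("numerical integrators converge to the closed form", {
  set.seed(42)
  k <- kinetic_params(k01 = 2e-3, k10 = 5e-4, k12 = 1e-3, k21 = 4e-4,
                      k13_young = 7e-4)
  cc <- 3; t_end <- 2000
  exact <- analytic_compartments(k, cc, t_end,
                                 compartment_state(Sl = 0.5, Ss = 0.2, Pl = 0.1))
  # exact propagator stepping reproduces the oracle for any step count
  st <- compartment_state(Sl = 0.5, Ss = 0.2, Pl = 0.1)
  for (i in 1:4) st <- step_compartments(st, cc, k, t_end / 4)$state
  expect_equal(st$Sl[1, 1], exact$Sl[1, 1], tolerance = 1e-12)
  expect_equal(st$Pl[1, 1], exact$Pl[1, 1], tolerance = 1e-12)

  # RK4 at moderate resolution
  st <- compartment_state(Sl = 0.5, Ss = 0.2, Pl = 0.1)
  st <- step_compartments(st, cc, k, t_end, method = "rk4", substeps = 200)$state
  expect_equal(st$Sl[1, 1], exact$Sl[1, 1], tolerance = 1e-9)

  # Euler is first-order global (second-order local, so one step and two
  # half-steps agree to O(dt^2)): halving the step halves the error
  err <- function(n) {
    st <- compartment_state(Sl = 0.5, Ss = 0.2, Pl = 0.1)
    st <- step_compartments(st, cc, k, t_end, method = "euler", substeps = n)$state
    abs(st$Sl[1, 1] - exact$Sl[1, 1])
  }
  ratio <- err(50) / err(100)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.4) # first-order global => halving dt halves the error
})

test_that("the rate matrix is dissipative for nonnegative constants", {
  set.seed(8)
  for (r in 1:50) {
    k <- kinetic_params(k01 = runif(1, 0, 1e-3), k10 = runif(1, 0, 1e-3),
                        k12 = runif(1, 0, 1e-3), k21 = runif(1, 0, 1e-3),
                        k13_young = runif(1, 0, 1e-3))
    A <- mangroveCr:::compartment_matrix(k, k$k13_young)
    expect_lte(max(Re(eigen(A, only.values = TRUE)$values)), 1e-12)
  }
})

test_that("water loses exactly what the pools gain (gamma closure)", {
  ctx <- soil_context()
  h <- 4
  gam <- gamma_factor(ctx, h)
  k <- kinetic_params(k01 = 1e-4, k10 = 2e-5, k12 = 5e-5, k21 = 1e-5,
                      k13_young = 3e-5)
  st <- compartment_state(Sl = 0.5, Ss = 0.1, Pl = 0)
  cc <- 2
  out <- step_compartments(st, cc, k, dt = 50, gamma = gam)
  dpool <- (out$state$Sl - st$Sl) + (out$state$Ss - st$Ss) + (out$state$Pl - st$Pl)
  # areal mass: pools via rho_b * zs / 1000, water via dc * h
  soil_areal <- ctx$bulk_density * ctx$active_layer_depth / 1000
  expect_equal(out$dc * h, -dpool * soil_areal, tolerance = 1e-14)
})

test_that("dry cells are inert and plant chromium never decreases", {
  k <- kinetic_params()
  st <- compartment_state(Sl = matrix(1, 2, 2), Ss = matrix(0.5, 2, 2),
                          Pl = matrix(0.1, 2, 2))
  wet <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  out <- step_compartments(st, 1, k, dt = 3600, wet = wet)
  expect_identical(out$state$Sl[!wet], st$Sl[!wet])
  expect_identical(out$state$Ss[!wet], st$Ss[!wet])
  expect_identical(out$state$Pl[!wet], st$Pl[!wet])
  expect_identical(out$dc[!wet], c(0, 0))

  # k13 = 0 freezes the plant pool
  out0 <- step_compartments(st, 1, k, dt = 3600, k13 = 0)
  expect_identical(out0$state$Pl, st$Pl)

  # monotone uptake along a trajectory
  traj <- analytic_compartments(kinetic_params(), 5,
                                seq(0, 1e7, length.out = 30))
  expect_true(all(diff(traj$Pl) >= 0))
})

test_that("young mangroves dominate mature ones under identical forcing", {
  k <- kinetic_params() # k13_young = 7e-8 > k13_mature = 7e-9
  times <- seq(0, 2e6, length.out = 10)[-1]
  young <- analytic_compartments(k, 1, times, k13 = k$k13_young)
  mature <- analytic_compartments(k, 1, times, k13 = k$k13_mature)
  expect_true(all(young$Pl > mature$Pl))
})

test_that("uptake rate field averages the plant pool over the window", {
  fake <- list(snapshot_times = c(0, 86400, 3 * 86400),
               snapshots = list(Pl = list(matrix(0, 2, 2),
                                          matrix(1, 2, 2),
                                          matrix(4, 2, 2))))
  r <- uptake_rate_field(fake, c(86400, 3 * 86400))
  expect_equal(r, matrix(1.5, 2, 2)) # 3 mg/kg over 2 days
  expect_equal(uptake_rate_field(fake, c(0, 86400)), matrix(1, 2, 2))
  const <- list(snapshot_times = c(0, 86400),
                snapshots = list(Pl = list(matrix(2, 1, 1), matrix(2, 1, 1))))
  expect_equal(uptake_rate_field(const, c(0, 86400)), matrix(0, 1, 1))
  expect_error(uptake_rate_field(fake, c(0, 5 * 86400)), "outside")
  expect_error(uptake_rate_field(fake, c(86400, 86400)), "exceed")
})
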