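# helper: a steady uniform-flow hydro pair for a flat channel (depth h0,
# velocity u0 everywhere), with the face fluxes step_transport expects
uniform_flow <- function(grid, h0, u0, dt) {
  prev <- hydro_state(grid, zeta = h0 - grid$bed_depth[1, 1], u = u0)
  cur <- prev; cur$t <- prev$t + dt
  qx <- matrix(h0 * u0, grid$nx + 1, grid$ny)
  qx[1, ] <- qx[grid$nx + 1, ] <- 0 # closed ends unless boundary cells exist
  attr(cur, "qx") <- qx
  attr(cur, "qy") <- matrix(0, grid$nx, grid$ny + 1)
  list(prev = prev, cur = cur)
}

test_that("point sources are gated by their daily window and ledgered exactly", {
  g <- make_grid(5, 1, 100, 100, 10, "riverbed")
  st <- transport_state(g)
  src <- list(discharge_source("GoDau", 3, 1, rate = 2)) # mg/s, 12:00-14:00
  h <- matrix(10, 5, 1)

  # full day: 2 mg/s x 7200 s = 14.4 g
  out <- apply_sources(st, src, t = 0, dt = 86400, grid = g, h = h)
  expect_equal(attr(out, "mass_added"), 14.4)
  expect_equal(out$c[3, 1], 14.4 / (10 * 100 * 100))
  expect_equal(sum(out$c), out$c[3, 1]) # only the source cell gains

  # outside the window: unchanged
  out2 <- apply_sources(st, src, t = 0, dt = 3600, grid = g, h = h)
  expect_identical(out2$c, st$c)
  expect_equal(attr(out2, "mass_added"), 0)

  # partial overlap is exact: 12:30-13:00 over a step covering 12:00-12:45
  sec <- mangroveCr:::window_overlap(12 * 3600, 12.75 * 3600, c(12.5, 13))
  expect_equal(sec, 900)

  # ledger equals rate x active seconds across arbitrary step tilings
  set.seed(7)
  total <- 0; t <- 0
  while (t < 2 * 86400) {
    dt <- runif(1, 600, 7000)
    o <- apply_sources(st, src, t, dt, g, h)
    total <- total + attr(o, "mass_added")
    t <- t + dt
  }
  expect_equal(total, 2 * mangroveCr:::window_overlap(0, t, c(12, 14)) * 1e-3)

  expect_error(apply_sources(st, list(discharge_source("x", 9, 1, 1)),
                             0, 86400, g, h), "outside the grid")
})

test_that("exchange term is linear, gated by wetness, and unit-converted", {
  k <- kinetic_params(k01 = 0.1, k10 = 0)
  expect_equal(exchange_terms(0, 0, k), 0)
  expect_equal(exchange_terms(1, 5, k), -0.1) # k10 = 0, gamma = 1
  expect_equal(exchange_terms(1, 5, k, wet = FALSE), 0) # no exchange when dry
  k2 <- kinetic_params(k01 = 0.02, k10 = 0.004)
  expect_equal(exchange_terms(2, 3, k2, gamma = 0.5),
               0.5 * (-0.02 * 2 + 0.004 * 3))
  kbad <- kinetic_params(); kbad$k01 <- -1
  expect_error(exchange_terms(1, 1, kbad), ">= 0")
})

test_that("null dynamics: a zero field stays zero", {
  g <- make_grid(20, 1, 10, 10, 1, "riverbed")
  uf <- uniform_flow(g, h0 = 1, u0 = 0.5, dt = 5)
  st <- transport_state(g)
  out <- step_transport(st, uf$cur, uf$prev, g, transport_params(Dx = 5, Dy = 5), dt = 5)
  expect_identical(max(abs(out$c)), 0)
})

test_that("upwind advection at unit Courant number is an exact shift", {
  g <- make_grid(30, 1, 10, 10, 1, "riverbed")
  u0 <- 0.5; dt <- 10 / u0 # CFL exactly 1
  uf <- uniform_flow(g, 1, u0, dt)
  cstep <- matrix(0, 30, 1); cstep[5:10, 1] <- 2
  st <- transport_state(g, cstep)
  out <- step_transport(st, uf$cur, uf$prev, g, transport_params(Dx = 0, Dy = 0), dt = dt)
  shifted <- matrix(0, 30, 1); shifted[6:11, 1] <- 2
  expect_equal(out$c, shifted, tolerance = 1e-14)
})

test_that("advection translates a profile at the flow speed (Galilean check)", {
  g <- make_grid(200, 1, 10, 10, 1, "riverbed")
  u0 <- 0.4; dt <- 5
  x <- (seq_len(200) - 0.5) * 10
  prof <- matrix(exp(-((x - 500) / 60)^2), 200, 1)
  st <- transport_state(g, prof)
  uf <- uniform_flow(g, 1, u0, dt)
  nsteps <- 400 # u t = 800 m
  for (s in seq_len(nsteps)) {
    st <- step_transport(st, uf$cur, uf$prev, g, transport_params(Dx = 0, Dy = 0), dt = dt)
  }
  com0 <- sum(x * prof) / sum(prof)
  com1 <- sum(x * st$c) / sum(st$c)
  expect_lt(abs((com1 - com0) - u0 * nsteps * dt), g$dx) # within one cell
  expect_true(all(st$c >= 0))
})

test_that("compiled and reference transport kernels agree on random states", {
  set.seed(21)
  tc <- small_catchment()
  g <- tc$grid
  p <- transport_params()
  wsh <- mangroveCr:::hydro_workspace(g, hydro_params(), tc$tide, tc$discharge)
  wst <- mangroveCr:::transport_workspace(g, p, inflow = wsh$inflow)
  for (rep in 1:5) {
    m <- matrix(runif(g$nx * g$ny, 0, 2), g$nx, g$ny) * wst$interior
    h0 <- matrix(runif(g$nx * g$ny, 0.005, 12), g$nx, g$ny)
    qx <- matrix(runif((g$nx + 1) * g$ny, -1, 1), g$nx + 1, g$ny)
    qy <- matrix(runif(g$nx * (g$ny + 1), -1, 1), g$nx, g$ny + 1)
    a <- mangroveCr:::transport_core(m, h0, qx, qy, 2, wst, core = "cpp")
    b <- mangroveCr:::transport_core(m, h0, qx, qy, 2, wst, core = "r")
    expect_equal(a$m, b$m, tolerance = 1e-13)
    expect_equal(a$exported, b$exported, tolerance = 1e-13)
    expect_equal(a$imported, b$imported, tolerance = 1e-13)
    expect_true(min(a$m) >= 0)
  }
})

test_that("transport conserves mass against the boundary ledger", {
  set.seed(31)
  tc <- small_catchment()
  g <- tc$grid
  wsh <- mangroveCr:::hydro_workspace(g, hydro_params(), tc$tide, tc$discharge)
  wst <- mangroveCr:::transport_workspace(g, transport_params(), inflow = wsh$inflow)
  m <- matrix(runif(g$nx * g$ny, 0, 2), g$nx, g$ny) * wst$interior
  h0 <- matrix(runif(g$nx * g$ny, 0.5, 12), g$nx, g$ny)
  qx <- matrix(runif((g$nx + 1) * g$ny, -1, 1), g$nx + 1, g$ny)
  qy <- matrix(runif(g$nx * (g$ny + 1), -1, 1), g$nx, g$ny + 1)
  tot0 <- sum(m) * g$dx * g$dy
  out <- mangroveCr:::transport_core(m, h0, qx, qy, 3, wst)
  tot1 <- sum(out$m) * g$dx * g$dy
  expect_equal(tot1 + out$exported - out$imported, tot0,
               tolerance = 1e-12)
})

test_that("stability violations are rejected rather than integrated", {
  g <- make_grid(20, 1, 10, 10, 1, "riverbed")
  uf <- uniform_flow(g, 1, 0.5, 100)
  st <- transport_state(g, 1)
  expect_error(
    step_transport(st, uf$cur, uf$prev, g, transport_params(Dx = 10), dt = 100),
    "stability|CFL")
})
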