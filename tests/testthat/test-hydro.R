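test_that("Chezy coefficient and quadratic bed shear match their closed forms", {
  expect_equal(chezy(1, 1), 1)
  expect_equal(chezy(64, 0.005), 400) # 64^(1/6) = 2
  expect_error(chezy(0, 0.005), "positive")
  expect_error(chezy(1, 0), "positive")

  expect_equal(bed_shear(0, 0, 5, 0.02), list(taux = 0, tauy = 0))
  ts <- bed_shear(1, 0, 1, 1, g = 9.81, rho_w = 1000)
  expect_equal(ts$taux, 9810)
  expect_equal(ts$tauy, 0)
  # swapping (u, v) swaps the components
  a <- bed_shear(0.7, -0.3, 4, 0.05); b <- bed_shear(-0.3, 0.7, 4, 0.05)
  expect_equal(a$taux, b$tauy)
  expect_equal(a$tauy, b$taux)
  # shear opposes the velocity componentwise
  set.seed(4)
  for (r in 1:20) {
    u <- runif(1, -2, 2); v <- runif(1, -2, 2)
    s <- bed_shear(u, v, runif(1, 0.5, 20), runif(1, 0.005, 0.15))
    expect_gte(s$taux * u, 0)
    expect_gte(s$tauy * v, 0)
  }
})

test_that("harmonic tide synthesis evaluates each constituent independently", {
  tb <- tide_boundary(amplitude = 2.7, period = 12.42 * 3600, phase = 0)
  expect_equal(tide_elevation(tb, 0), 2.7)
  expect_equal(tide_elevation(tb, 12.42 * 3600 / 4), 0, tolerance = 1e-12)
  tb2 <- tide_boundary(amplitude = c(2.7, 0.5), period = c(12.42, 24) * 3600,
                       phase = c(0.3, 1.1), mean_level = 0.2)
  t <- c(0, 5000, 20000)
  expected <- 0.2 + 2.7 * cos(2 * pi * t / (12.42 * 3600) - 0.3) +
    0.5 * cos(2 * pi * t / (24 * 3600) - 1.1)
  expect_equal(tide_elevation(tb2, t), expected)
})

test_that("CFL bound scales with resolution, depth and velocity", {
  g <- make_grid(4, 4, 100, 100, 10, "riverbed")
  p <- hydro_params(cfl = 0.7)
  st <- hydro_state(g)
  expect_equal(courant_dt(g, st, p), 0.7 * 100 / sqrt(9.81 * 10))
  g2 <- make_grid(4, 4, 200, 200, 10, "riverbed")
  expect_equal(courant_dt(g2, hydro_state(g2), p), 2 * courant_dt(g, st, p))
  st_u <- hydro_state(g, u = 1)
  expect_lt(courant_dt(g, st_u, p), courant_dt(g, st, p))
  g_dry <- make_grid(4, 4, 100, 100, -1, "bare")
  expect_error(courant_dt(g_dry, hydro_state(g_dry), p), "dry")
})

test_that("a lake at rest stays at rest over variable bathymetry", {
  # channel plus banks above datum: uniform surface, zero velocity
  tc <- small_catchment()
  g <- tc$grid
  p <- hydro_params()
  st <- hydro_state(g, zeta = 0.2) # floods nothing (banks at -0.5 need > 0.51)
  s1 <- step_hydro(st, g, p, dt = 4)
  expect_identical(max(abs(s1$zeta - st$zeta)), 0)
  expect_identical(max(abs(s1$u)), 0)
  expect_identical(max(abs(s1$v)), 0)
})

test_that("closed-basin water volume is conserved to rounding while sloshing", {
  g <- basin_grid(nx = 40, ny = 3)
  p <- hydro_params(f = 0)
  x <- (seq_len(g$nx) - 0.5) * g$dx
  tilt <- matrix(rep(0.3 * (2 * x / (g$nx * g$dx) - 1), g$ny), g$nx, g$ny)
  st <- hydro_state(g, zeta = tilt)
  v0 <- water_volume(g, st)
  drift <- 0
  out <- run_hydro(g, st, p, dt = 5, n = 400, each = function(s, zeta, u, v) {
    vol <- sum(pmax(g$bed_depth + zeta, 0)) * g$dx * g$dy
    drift <<- max(drift, abs(vol - v0) / v0)
  })
  expect_lt(drift, 1e-12)
})

test_that("dry cells carry no momentum except through flooding faces", {
  tc <- small_catchment()
  g <- tc$grid
  p <- hydro_params()
  ws <- mangroveCr:::hydro_workspace(g, p, tc$tide, tc$discharge)
  zeta <- matrix(0, g$nx, g$ny); u <- matrix(0, g$nx + 1, g$ny); v <- matrix(0, g$nx, g$ny + 1)
  dt <- 8
  ok <- TRUE
  for (s in 1:600) { # spans flooding and draining of the banks
    o <- mangroveCr:::hydro_step_core(zeta, u, v, (s - 1) * dt, dt, ws)
    zeta <- o$zeta; u <- o$u; v <- o$v
    wet <- wet_mask(g, zeta, p$h_dry)
    dry <- !wet
    # a face bordering a dry cell may only flow while the face water level
    # stands above the higher bed (the flooding head); otherwise it is closed
    d <- g$bed_depth
    hfx <- pmax(zeta[1:(g$nx - 1), , drop = FALSE], zeta[2:g$nx, , drop = FALSE]) +
      pmin(d[1:(g$nx - 1), , drop = FALSE], d[2:g$nx, , drop = FALSE])
    ub <- u[2:g$nx, , drop = FALSE]
    closed <- (dry[1:(g$nx - 1), , drop = FALSE] | dry[2:g$nx, , drop = FALSE]) &
      (hfx <= p$h_dry)
    if (any(ub[closed] != 0)) { ok <- FALSE; break }
    # both-dry pairs never flow, with or without flooding head
    bothdry <- dry[1:(g$nx - 1), , drop = FALSE] & dry[2:g$nx, , drop = FALSE]
    if (any(ub[bothdry & hfx <= p$h_dry] != 0)) { ok <- FALSE; break }
    hfy <- pmax(zeta[, 1:(g$ny - 1), drop = FALSE], zeta[, 2:g$ny, drop = FALSE]) +
      pmin(d[, 1:(g$ny - 1), drop = FALSE], d[, 2:g$ny, drop = FALSE])
    vb <- v[, 2:g$ny, drop = FALSE]
    closedv <- (dry[, 1:(g$ny - 1), drop = FALSE] | dry[, 2:g$ny, drop = FALSE]) &
      (hfy <= p$h_dry)
    if (any(vb[closedv] != 0)) { ok <- FALSE; break }
  }
  expect_true(ok)
})

test_that("without rotation a symmetric basin keeps its symmetry axis", {
  g <- basin_grid(nx = 30, ny = 6)
  p <- hydro_params(f = 0)
  x <- (seq_len(g$nx) - 0.5) * g$dx
  tilt <- matrix(rep(0.2 * sin(pi * x / (g$nx * g$dx)), g$ny), g$nx, g$ny)
  st <- hydro_state(g, zeta = tilt) # symmetric across the channel axis
  out <- run_hydro(g, st, p, dt = 5, n = 300)
  expect_equal(out$zeta, out$zeta[, g$ny:1], tolerance = 1e-13)
})

test_that("compiled and reference kernels agree step-by-step through wet/dry tides", {
  tc <- small_catchment()
  g <- tc$grid
  p <- hydro_params()
  ws <- mangroveCr:::hydro_workspace(g, p, tc$tide, tc$discharge)
  zc <- zr <- matrix(0, g$nx, g$ny)
  uc <- ur <- matrix(0, g$nx + 1, g$ny)
  vc <- vr <- matrix(0, g$nx, g$ny + 1)
  dt <- 8
  maxdiff <- 0
  for (s in 1:500) {
    oc <- mangroveCr:::hydro_step_core(zc, uc, vc, (s - 1) * dt, dt, ws, core = "cpp")
    or <- mangroveCr:::hydro_step_core(zr, ur, vr, (s - 1) * dt, dt, ws, core = "r")
    zc <- oc$zeta; uc <- oc$u; vc <- oc$v
    zr <- or$zeta; ur <- or$u; vr <- or$v
    maxdiff <- max(maxdiff, abs(zc - zr), abs(uc - ur), abs(vc - vr),
                   abs(oc$qx - or$qx), abs(oc$qy - or$qy))
  }
  expect_lt(maxdiff, 1e-12)
})

test_that("step_hydro rejects steps beyond the CFL bound", {
  g <- basin_grid(nx = 10, ny = 2)
  st <- hydro_state(g)
  expect_error(step_hydro(st, g, hydro_params(), dt = 60), "CFL")
})
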