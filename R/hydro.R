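#' Hydrodynamic parameters
#'
#' Physical parameters of the depth-averaged shallow-water solver.
#'
#' @param g Gravitational acceleration (m/s^2).
#' @param f Coriolis parameter (1/s). Default corresponds to latitude
#'   10.5 deg N, `f = 2 * Omega * sin(lat)`.
#' @param K Horizontal eddy viscosity (m^2/s). The calibrated value 1 m^2/s
#'   is the default.
#' @param rho_w Water density (kg/m^3).
#' @param Fx,Fy External surface force fields (N/m^2), scalar or cell matrix;
#'   default zero (no wind/wave forcing).
#' @param h_dry Drying threshold (m): faces close when the face water depth
#'   falls below this.
#' @param cfl Courant safety factor (<= 1) used by [courant_dt()].
#' @return Object of class `hydro_params`.
#' @export
hydro_params <- function(g = 9.81, f = 2 * 7.292115e-5 * sin(10.5 * pi / 180),
                         K = 1, rho_w = 1000, Fx = 0, Fy = 0,
                         h_dry = 0.01, cfl = 0.7) {
  if (!(g > 0)) stop("g must be positive")
  if (K < 0) stop("K must be >= 0")
  if (!(rho_w > 0)) stop("rho_w must be positive")
  if (!(h_dry > 0)) stop("h_dry must be positive")
  if (!(cfl > 0 && cfl <= 1)) stop("cfl must be in (0, 1]")
  structure(list(g = g, f = f, K = K, rho_w = rho_w, Fx = Fx, Fy = Fy,
                 h_dry = h_dry, cfl = cfl),
            class = "hydro_params")
}

#' Initial hydrodynamic state
#'
#' Surface elevation at cell centers and depth-averaged velocities on cell
#' faces (Arakawa C staggering): `u` on the `(nx+1) x ny` x-normal faces,
#' `v` on the `nx x (ny+1)` y-normal faces.
#'
#' @param grid A [make_grid()] object.
#' @param zeta Initial surface elevation (m), scalar or `nx` x `ny` matrix.
#' @param u,v Initial face velocities (m/s), scalar or face matrices.
#' @param t Initial time (s).
#' @return Object of class `hydro_state` with fields `zeta`, `u`, `v`, `t`.
#' @export
hydro_state <- function(grid, zeta = 0, u = 0, v = 0, t = 0) {
  nx <- grid$nx; ny <- grid$ny
  expand <- function(x, nr, nc, what) {
    if (length(x) == 1) x <- matrix(x, nr, nc)
    if (!is.matrix(x) || nrow(x) != nr || ncol(x) != nc) {
      stop(sprintf("%s must be %d x %d", what, nr, nc))
    }
    x
  }
  structure(list(zeta = expand(zeta, nx, ny, "zeta"),
                 u = expand(u, nx + 1, ny, "u"),
                 v = expand(v, nx, ny + 1, "v"),
                 t = t),
            class = "hydro_state")
}

#' Chezy coefficient from depth and Manning roughness
#'
#' `C = h^(1/6) / n` for depth-averaged flow. Callers must gate on wet cells:
#' non-positive depth is rejected.
#'
#' @param h Total water depth (m), > 0. Vectorized.
#' @param n Manning roughness (s m^-1/3), > 0.
#' @return Chezy coefficient(s) (m^(1/2)/s).
#' @examples
#' chezy(64, 0.005) # 400
#' @export
chezy <- function(h, n) {
  if (any(h <= 0)) stop("chezy: total depth h must be positive (wet cells only)")
  if (any(n <= 0)) stop("chezy: Manning n must be positive")
  h^(1 / 6) / n
}

#' Quadratic-law bed shear stress
#'
#' `tau_bx = rho_w g |U| u / C^2`, `tau_by = rho_w g |U| v / C^2` with
#' `C = chezy(h, n)` and `|U| = sqrt(u^2 + v^2)`. The shear always opposes
#' the velocity.
#'
#' @param u,v Depth-averaged velocity components (m/s).
#' @param h Total water depth (m), > 0.
#' @param n Manning roughness (s m^-1/3).
#' @param g Gravitational acceleration (m/s^2).
#' @param rho_w Water density (kg/m^3).
#' @return List with components `taux`, `tauy` (N/m^2).
#' @export
bed_shear <- function(u, v, h, n, g = 9.81, rho_w = 1000) {
  C <- chezy(h, n)
  speed <- sqrt(u^2 + v^2)
  list(taux = rho_w * g * speed * u / C^2,
       tauy = rho_w * g * speed * v / C^2)
}

# Cell-centered velocity magnitudes from face velocities.
cell_speed <- function(state, nx, ny) {
  ucc <- 0.5 * (state$u[1:nx, , drop = FALSE] + state$u[2:(nx + 1), , drop = FALSE])
  vcc <- 0.5 * (state$v[, 1:ny, drop = FALSE] + state$v[, 2:(ny + 1), drop = FALSE])
  sqrt(ucc^2 + vcc^2)
}

#' Maximal stable time step (CFL bound)
#'
#' Explicit-scheme stability bound
#' `dt <= cfl * min(dx, dy) / max_wet(sqrt(g h) + |U|)`.
#'
#' @param grid A [make_grid()] object.
#' @param state A [hydro_state()].
#' @param params A [hydro_params()].
#' @return Time step in seconds.
#' @export
courant_dt <- function(grid, state, params = hydro_params()) {
  h <- grid$bed_depth + state$zeta
  wet <- wet_mask(grid, state$zeta, params$h_dry)
  if (!any(wet)) stop("courant_dt: all cells are dry")
  speed <- cell_speed(state, grid$nx, grid$ny)
  celerity <- sqrt(params$g * h[wet]) + speed[wet]
  params$cfl * min(grid$dx, grid$dy) / max(celerity)
}

# Precompute static solver topology: face pair masks, face Manning values,
# tide-cell indices and inflow-face bookkeeping.
hydro_workspace <- function(grid, params, boundary = NULL, discharge = 0) {
  nx <- grid$nx; ny <- grid$ny
  d <- grid$bed_depth
  act <- grid$active
  if (nx < 2) stop("hydrodynamics requires nx >= 2")

  ws <- list(nx = nx, ny = ny, dx = grid$dx, dy = grid$dy, d = d,
             active = act, params = params, boundary = boundary,
             discharge = discharge)
  ia <- 1:(nx - 1); ib <- 2:nx
  ws$ia <- ia; ws$ib <- ib
  ws$pairx <- act[ia, , drop = FALSE] & act[ib, , drop = FALSE]
  ws$nfx <- 0.5 * (grid$manning[ia, , drop = FALSE] + grid$manning[ib, , drop = FALSE])
  ws$dminx <- pmin(d[ia, , drop = FALSE], d[ib, , drop = FALSE])
  if (ny >= 2) {
    ja <- 1:(ny - 1); jb <- 2:ny
    ws$ja <- ja; ws$jb <- jb
    ws$pairy <- act[, ja, drop = FALSE] & act[, jb, drop = FALSE]
    ws$nfy <- 0.5 * (grid$manning[, ja, drop = FALSE] + grid$manning[, jb, drop = FALSE])
    ws$dminy <- pmin(d[, ja, drop = FALSE], d[, jb, drop = FALSE])
  }

  ob <- grid$open_boundary
  tide <- ob[ob$kind == "tide", , drop = FALSE]
  ws$tide_idx <- if (nrow(tide) > 0) cbind(tide$i, tide$j) else NULL
  inflow <- ob[ob$kind == "inflow", , drop = FALSE]
  if (nrow(inflow) > 0) {
    # edge orientation of each inflow cell; flux is directed into the domain
    side <- ifelse(inflow$j == ny, "N",
            ifelse(inflow$j == 1, "S",
            ifelse(inflow$i == nx, "E", "W")))
    ws$inflow <- data.frame(i = inflow$i, j = inflow$j, side = side,
                            stringsAsFactors = FALSE)
    ws$q_per_cell <- discharge / nrow(inflow) # m^3/s through each inflow cell
  } else {
    ws$inflow <- NULL
  }
  ws$ext <- !act # exterior mask
  # shift index vectors for edge-replicated neighbours on face arrays
  if (ny >= 2) {
    ws$jm1 <- c(1L, 1:(ny - 1L)); ws$jp1 <- c(2:ny, ny)
    ws$im1 <- c(1L, 1:(nx - 1L)); ws$ip1 <- c(2:nx, nx)
  }
  if (!is.null(boundary)) {
    ws$tide_A <- boundary$amplitude; ws$tide_T <- boundary$period
    ws$tide_phi <- boundary$phase; ws$tide_mean <- boundary$mean_level
    ws$tide_ramp <- boundary$ramp
  }
  # flattened arguments for the compiled kernel
  ws$tide_idx0 <- if (is.null(ws$tide_idx)) {
    matrix(0L, 0, 2)
  } else {
    matrix(as.integer(ws$tide_idx - 1L), ncol = 2)
  }
  ws$has_force <- is.matrix(params$Fx) || is.matrix(params$Fy) ||
    params$Fx != 0 || params$Fy != 0
  expandf <- function(x) if (is.matrix(x)) x else matrix(x, nx, ny)
  ws$Fxm <- if (ws$has_force) expandf(params$Fx) else matrix(0, 1, 1)
  ws$Fym <- if (ws$has_force) expandf(params$Fy) else matrix(0, 1, 1)
  if (!is.null(ws$inflow)) {
    ws$infl_i <- as.integer(ws$inflow$i - 1L)
    ws$infl_j <- as.integer(ws$inflow$j - 1L)
    ws$infl_side <- match(ws$inflow$side, c("N", "S", "E", "W")) - 1L
  } else {
    ws$infl_i <- integer(0); ws$infl_j <- integer(0); ws$infl_side <- integer(0)
    ws$q_per_cell <- 0
  }
  ws$grid_manning <- grid$manning
  ws
}

# Kernel dispatcher: the compiled core is the default; the vectorized R
# reference kernel remains available for cross-checking.
hydro_step_core <- function(zeta, u, v, t, dt, ws, core = c("cpp", "r")) {
  core <- match.arg(core)
  if (core == "r") return(hydro_step_core_r(zeta, u, v, t, dt, ws))
  p <- ws$params
  has_tide <- nrow(ws$tide_idx0) > 0 && !is.null(ws$boundary)
  tide_level <- if (has_tide) tide_eval(ws, t + dt) else 0
  tidx <- if (has_tide) ws$tide_idx0 else matrix(0L, 0, 2)
  hydro_step_cpp(zeta, u, v, dt, ws$d, ws$active, ws$grid_manning,
                 p$g, p$f, p$K, p$rho_w, ws$Fxm, ws$Fym, ws$has_force,
                 p$h_dry, ws$dx, ws$dy, tidx, tide_level,
                 ws$infl_i, ws$infl_j, ws$infl_side, ws$q_per_cell %||% 0)
}

# scalar tidal elevation without S3/vapply overhead, for the inner loop
tide_eval <- function(ws, t) {
  z <- sum(ws$tide_A * cos(2 * pi * t / ws$tide_T - ws$tide_phi))
  if (ws$tide_ramp > 0) {
    f <- min(1, max(0, t / ws$tide_ramp))
    z <- z * sin(0.5 * pi * f)^2
  }
  ws$tide_mean + z
}

# Prescribe inflow-face velocities from the current elevation field.
# Returns modified u, v. Positive discharge always flows into the domain.
apply_inflow_faces <- function(u, v, zeta, ws) {
  inf <- ws$inflow
  if (is.null(inf)) return(list(u = u, v = v))
  hd <- ws$params$h_dry
  for (r in seq_len(nrow(inf))) {
    i <- inf$i[r]; j <- inf$j[r]
    h <- max(ws$d[i, j] + zeta[i, j], hd)
    if (inf$side[r] == "N") v[i, j + 1] <- -ws$q_per_cell / (ws$dx * h)
    else if (inf$side[r] == "S") v[i, 1] <- ws$q_per_cell / (ws$dx * h)
    else if (inf$side[r] == "E") u[i + 1, j] <- -ws$q_per_cell / (ws$dy * h)
    else u[1, j] <- ws$q_per_cell / (ws$dy * h)
  }
  list(u = u, v = v)
}

# One forward-backward step of the shallow-water equations (R reference
# kernel). Returns list(zeta, u, v, qx, qy): qx, qy are the face volume
# fluxes per unit width (m^2/s) actually used in the continuity update, for
# reuse by the transport solver and the volume budget.
hydro_step_core_r <- function(zeta, u, v, t, dt, ws) {
  p <- ws$params
  nx <- ws$nx; ny <- ws$ny; dx <- ws$dx; dy <- ws$dy
  ia <- ws$ia; ib <- ws$ib
  hd <- p$h_dry
  g <- p$g; fcor <- p$f; K <- p$K
  has_y <- ny >= 2

  bv <- apply_inflow_faces(u, v, zeta, ws)
  u <- bv$u; v <- bv$v

  # --- face depths and open masks from the current surface -----------------
  zfx <- pmax.int(zeta[ia, , drop = FALSE], zeta[ib, , drop = FALSE])
  hfx <- zfx + ws$dminx
  openx <- ws$pairx & (hfx > hd)
  uin <- u[ib, , drop = FALSE]
  uin[!openx] <- 0
  qx <- matrix(0, nx + 1, ny)
  qx[ib, ] <- hfx * uin

  if (has_y) {
    ja <- ws$ja; jb <- ws$jb
    zfy <- pmax.int(zeta[, ja, drop = FALSE], zeta[, jb, drop = FALSE])
    hfy <- zfy + ws$dminy
    openy <- ws$pairy & (hfy > hd)
    vin <- v[, jb, drop = FALSE]
    vin[!openy] <- 0
    qy <- matrix(0, nx, ny + 1)
    qy[, jb] <- hfy * vin
  } else {
    qy <- matrix(0, nx, 2)
  }

  # inflow boundary faces carry their prescribed flux
  inf <- ws$inflow
  if (!is.null(inf)) {
    for (r in seq_len(nrow(inf))) {
      i <- inf$i[r]; j <- inf$j[r]
      h <- max(ws$d[i, j] + zeta[i, j], hd)
      if (inf$side[r] == "N") qy[i, j + 1] <- v[i, j + 1] * h
      else if (inf$side[r] == "S") qy[i, 1] <- v[i, 1] * h
      else if (inf$side[r] == "E") qx[i + 1, j] <- u[i + 1, j] * h
      else qx[1, j] <- u[1, j] * h
    }
  }

  # --- positivity limiter: a cell may not export more volume than it holds --
  h <- ws$d + zeta
  out <-(pmax(qx[2:(nx + 1), , drop = FALSE], 0) + pmax(-qx[1:nx, , drop = FALSE], 0)) / dx +
         (pmax(qy[, 2:(ny + 1), drop = FALSE], 0) + pmax(-qy[, 1:ny, drop = FALSE], 0)) / dy
  need <- out * dt > 0.9 * pmax(h, 0)
  if (any(need & ws$active)) {
    s <- matrix(1, nx, ny)
    sel <- need & ws$active
    s[sel] <- pmax.int(0.9 * h[sel], 0) / (out[sel] * dt)
    qxi <- qx[ib, , drop = FALSE]
    px <- (qxi > 0)
    qx[ib, ] <- qxi * (px * s[ia, , drop = FALSE] + (!px) * s[ib, , drop = FALSE])
    if (has_y) {
      qyi <- qy[, ws$jb, drop = FALSE]
      py <- (qyi > 0)
      qy[, ws$jb] <- qyi * (py * s[, ws$ja, drop = FALSE] + (!py) * s[, ws$jb, drop = FALSE])
    }
  }

  # --- continuity (forward) -------------------------------------------------
  div <- (qx[2:(nx + 1), , drop = FALSE] - qx[1:nx, , drop = FALSE]) / dx +
         (qy[, 2:(ny + 1), drop = FALSE] - qy[, 1:ny, drop = FALSE]) / dy
  zeta_new <- zeta - dt * div
  zeta_new[!ws$active] <- zeta[!ws$active]
  if (!is.null(ws$tide_idx) && !is.null(ws$boundary)) {
    zeta_new[ws$tide_idx] <- tide_eval(ws, t + dt)
  }
  if (!all(is.finite(zeta_new))) {
    bad <- which(!is.finite(zeta_new), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite surface elevation at cell (%d, %d), t = %.1f s",
                 bad[1], bad[2], t + dt))
  }

  # --- u momentum (backward: uses zeta_new) ---------------------------------
  zfx <- pmax.int(zeta_new[ia, , drop = FALSE], zeta_new[ib, , drop = FALSE])
  hfx <- zfx + ws$dminx
  openx <- ws$pairx & (hfx > hd)
  hfx <- pmax.int(hfx, hd)
  gx <- (zeta_new[ib, , drop = FALSE] - zeta_new[ia, , drop = FALSE]) / dx
  if (has_y) {
    vbar <- 0.25 * (v[ia, 1:ny, drop = FALSE] + v[ib, 1:ny, drop = FALSE] +
                    v[ia, 2:(ny + 1), drop = FALSE] + v[ib, 2:(ny + 1), drop = FALSE])
  } else {
    vbar <- matrix(0, nx - 1, ny)
  }
  speed <- sqrt(uin^2 + vbar^2)
  Cf <- hfx^(1 / 6) / ws$nfx
  fric <- g * speed / (Cf^2 * hfx)
  # upwind advection of u by (u, vbar)
  dudx_m <- (u[ib, , drop = FALSE] - u[ia, , drop = FALSE]) / dx
  dudx_p <- (u[ib + 1, , drop = FALSE] - u[ib, , drop = FALSE]) / dx
  pu <- (uin > 0)
  dudx <- pu * dudx_m + (!pu) * dudx_p
  if (ny >= 2) {
    up <- uin[, ws$jm1, drop = FALSE]
    un <- uin[, ws$jp1, drop = FALSE]
  } else {
    up <- uin; un <- uin
  }
  pv <- (vbar > 0)
  dudy <- pv * (uin - up) / dy + (!pv) * (un - uin) / dy
  adv <- uin * dudx + vbar * dudy
  lap <- (u[ib + 1, , drop = FALSE] - 2 * uin + u[ia, , drop = FALSE]) / dx^2 +
         (un - 2 * uin + up) / dy^2
  u_new <- matrix(0, nx + 1, ny)
  rhs <- -g * gx + fcor * vbar - adv + K * lap
  if (is.matrix(p$Fx)) {
    rhs <- rhs + 0.5 * (p$Fx[ia, , drop = FALSE] + p$Fx[ib, , drop = FALSE]) / (p$rho_w * hfx)
  } else if (p$Fx != 0) {
    rhs <- rhs + p$Fx / (p$rho_w * hfx)
  }
  ui <- (uin + dt * rhs) / (1 + dt * fric)
  ui[!openx] <- 0
  u_new[ib, ] <- ui

  # --- v momentum -----------------------------------------------------------
  v_new <- matrix(0, nx, ny + 1)
  if (has_y) {
    ja <- ws$ja; jb <- ws$jb
    zfy <- pmax.int(zeta_new[, ja, drop = FALSE], zeta_new[, jb, drop = FALSE])
    hfy <- zfy + ws$dminy
    openy <- ws$pairy & (hfy > hd)
    hfy <- pmax.int(hfy, hd)
    gy <- (zeta_new[, jb, drop = FALSE] - zeta_new[, ja, drop = FALSE]) / dy
    ubar <- 0.25 * (u[1:nx, ja, drop = FALSE] + u[2:(nx + 1), ja, drop = FALSE] +
                    u[1:nx, jb, drop = FALSE] + u[2:(nx + 1), jb, drop = FALSE])
    speedv <- sqrt(vin^2 + ubar^2)
    Cfv <- hfy^(1 / 6) / ws$nfy
    fricv <- g * speedv / (Cfv^2 * hfy)
    dvdy_m <- (v[, jb, drop = FALSE] - v[, ja, drop = FALSE]) / dy
    dvdy_p <- (v[, jb + 1, drop = FALSE] - v[, jb, drop = FALSE]) / dy
    pvv <- (vin > 0)
    dvdy <- pvv * dvdy_m + (!pvv) * dvdy_p
    vw <- vin[ws$im1, , drop = FALSE]
    ve <- vin[ws$ip1, , drop = FALSE]
    puu <- (ubar > 0)
    dvdx <- puu * (vin - vw) / dx + (!puu) * (ve - vin) / dx
    advv <- ubar * dvdx + vin * dvdy
    lapv <- (ve - 2 * vin + vw) / dx^2 +
            (v[, jb + 1, drop = FALSE] - 2 * vin + v[, ja, drop = FALSE]) / dy^2
    rhsv <- -g * gy - fcor * ubar - advv + K * lapv
    if (is.matrix(p$Fy)) {
      rhsv <- rhsv + 0.5 * (p$Fy[, ja, drop = FALSE] + p$Fy[, jb, drop = FALSE]) / (p$rho_w * hfy)
    } else if (p$Fy != 0) {
      rhsv <- rhsv + p$Fy / (p$rho_w * hfy)
    }
    vi <- (vin + dt * rhsv) / (1 + dt * fricv)
    vi[!openy] <- 0
    v_new[, jb] <- vi
  }

  # keep prescribed inflow faces
  if (!is.null(inf)) {
    bv <- apply_inflow_faces(u_new, v_new, zeta_new, ws)
    u_new <- bv$u; v_new <- bv$v
  }

  list(zeta = zeta_new, u = u_new, v = v_new, qx = qx, qy = qy)
}

#' Advance the shallow-water state one time step
#'
#' Forward-backward explicit step on the C-grid: flux-form continuity with
#' upwind face depths and a positivity limiter, then momentum with upwind
#' advection, semi-implicit quadratic bed friction (Chezy-Manning), Coriolis,
#' eddy-viscosity Laplacian and optional external forces. Faces close when
#' the face water depth falls below `h_dry`; dry faces carry zero velocity.
#' Tide boundary cells receive Dirichlet elevation from `boundary`; inflow
#' boundary cells receive `discharge` partitioned uniformly across them.
#'
#' @param state A [hydro_state()].
#' @param grid A [make_grid()] object.
#' @param params A [hydro_params()].
#' @param boundary A [tide_boundary()] (required if the grid has tide cells).
#' @param dt Time step (s); must satisfy [courant_dt()].
#' @param discharge Upstream inflow (m^3/s) through the inflow cells.
#' @param check_cfl If TRUE (default), reject a step exceeding the CFL bound.
#' @return Updated `hydro_state`; face volume fluxes per unit width are
#'   attached as attributes `qx`, `qy` (m^2/s).
#' @export
step_hydro <- function(state, grid, params = hydro_params(), boundary = NULL,
                       dt, discharge = 0, check_cfl = TRUE) {
  if (check_cfl && dt > courant_dt(grid, state, params) + 1e-12) {
    stop(sprintf("dt = %g s exceeds the CFL bound %g s", dt,
                 courant_dt(grid, state, params)))
  }
  ws <- hydro_workspace(grid, params, boundary, discharge)
  out <- hydro_step_core(state$zeta, state$u, state$v, state$t, dt, ws)
  res <- structure(list(zeta = out$zeta, u = out$u, v = out$v, t = state$t + dt),
                   class = "hydro_state")
  attr(res, "qx") <- out$qx
  attr(res, "qy") <- out$qy
  res
}

#' Total water volume on active cells
#' @param grid A [make_grid()] object.
#' @param state A [hydro_state()].
#' @return Volume in m^3 (negative depths truncated at zero).
#' @export
water_volume <- function(grid, state) {
  h <- pmax(grid$bed_depth + state$zeta, 0)
  sum(h[grid$active]) * grid$dx * grid$dy
}
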