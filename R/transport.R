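#' Transport parameters
#'
#' @param Dx,Dy Horizontal dispersion coefficients (m^2/s, >= 0). Default
#'   10 m^2/s, a typical estuarine magnitude.
#' @param c_inflow Concentration carried by water entering through open
#'   boundaries (g/m^3), default 0.
#' @return Object of class `transport_params`.
#' @export
transport_params <- function(Dx = 10, Dy = 10, c_inflow = 0) {
  if (Dx < 0 || Dy < 0) stop("dispersion coefficients must be >= 0")
  if (c_inflow < 0) stop("c_inflow must be >= 0")
  structure(list(Dx = Dx, Dy = Dy, c_inflow = c_inflow),
            class = "transport_params")
}

#' Transport state: Cr concentration in water
#'
#' @param grid A [make_grid()] object.
#' @param c Concentration field (g/m^3, equals mg/L), scalar or matrix.
#' @param t Time (s).
#' @return Object of class `transport_state`.
#' @export
transport_state <- function(grid, c = 0, t = 0) {
  if (length(c) == 1) c <- matrix(c, grid$nx, grid$ny)
  if (any(c < 0)) stop("concentration must be >= 0")
  structure(list(c = c, t = t), class = "transport_state")
}

#' Industrial point discharge source
#'
#' A chromium point source at one grid cell, active during a daily clock
#' window (wastewater is released around the daily 12:00-14:00 slack).
#' Routing is either `"direct"` into the river cell or `"through_wetland"`,
#' in which case the load passes a constructed wetland unit before reaching
#' the river.
#'
#' @param name Source label.
#' @param i,j Grid cell indices of the discharge point.
#' @param rate Cr mass rate while active (mg/s, >= 0).
#' @param window Daily activity window in hours, length-2 within `[0, 24]`.
#' @param routing `"direct"` or `"through_wetland"`.
#' @param wetland_id Identifier of the wetland unit for
#'   `routing = "through_wetland"`.
#' @return Object of class `discharge_source`.
#' @export
discharge_source <- function(name, i, j, rate, window = c(12, 14),
                             routing = c("direct", "through_wetland"),
                             wetland_id = NA_integer_) {
  routing <- match.arg(routing)
  if (rate < 0) stop("rate must be >= 0")
  if (length(window) != 2 || any(window < 0) || any(window > 24) ||
      window[2] <= window[1]) {
    stop("window must be (start, end) hours within one day, end > start")
  }
  structure(list(name = name, i = as.integer(i), j = as.integer(j),
                 rate = rate, window = window, routing = routing,
                 wetland_id = wetland_id),
            class = "discharge_source")
}

# Seconds of [t0, t1) that fall inside the daily clock window (hours).
window_overlap <- function(t0, t1, window) {
  s0 <- window[1] * 3600; s1 <- window[2] * 3600
  total <- 0
  day <- floor(t0 / 86400)
  while (day * 86400 < t1) {
    a <- max(t0, day * 86400 + s0)
    b <- min(t1, day * 86400 + s1)
    if (b > a) total <- total + (b - a)
    day <- day + 1
  }
  total
}

#' Apply point sources to the water concentration field
#'
#' Each active source adds `rate * active_seconds` mg (converted to g) to its
#' cell's water column: `c` gains `mass / (h * dx * dy)`. Sources are gated
#' by the overlap of `[t, t + dt)` with their daily clock window. Mass
#' discharged into a momentarily dry cell is not added here (the scenario
#' engine buffers it until the cell rewets, so that no mass vanishes); the
#' skipped mass is reported in the `mass_buffered` attribute.
#'
#' @param state A [transport_state()].
#' @param sources List of [discharge_source()] objects (direct routing only;
#'   wetland-routed sources are handled by the scenario engine).
#' @param t,dt Interval start (s) and length (s).
#' @param grid A [make_grid()] object.
#' @param h Total depth field (m).
#' @param h_dry Drying threshold (m).
#' @return Updated `transport_state`, with attributes `mass_added` and
#'   `mass_buffered` (g).
#' @export
apply_sources <- function(state, sources, t, dt, grid, h, h_dry = 0.01) {
  cnew <- state$c
  added <- 0; buffered <- 0
  A <- grid$dx * grid$dy
  for (s in sources) {
    if (s$i < 1 || s$i > grid$nx || s$j < 1 || s$j > grid$ny) {
      stop("source cell outside the grid: ", s$name)
    }
    sec <- window_overlap(t, t + dt, s$window)
    if (sec <= 0) next
    mass <- s$rate * sec * 1e-3 # mg -> g
    if (h[s$i, s$j] > h_dry && grid$active[s$i, s$j]) {
      cnew[s$i, s$j] <- cnew[s$i, s$j] + mass / (h[s$i, s$j] * A)
      added <- added + mass
    } else {
      buffered <- buffered + mass
    }
  }
  out <- state
  out$c <- cnew
  attr(out, "mass_added") <- added
  attr(out, "mass_buffered") <- buffered
  out
}

#' Water-side exchange term of the coupled model
#'
#' Source/sink of dissolved Cr from the soil coupling,
#' `gamma * (-k01 c + k10 Sl)` (g/m^3/s) on wet cells and zero on dry cells:
#' the soil-plant system exchanges with the water column only while
#' inundated.
#'
#' @param c Water concentration field (g/m^3).
#' @param Sl Soil liquid pool field (mg/kg).
#' @param k A [kinetic_params()].
#' @param wet Logical wet mask (default all wet).
#' @param gamma Unit conversion factor (see [gamma_factor()]; default 1).
#' @return Field of concentration rates (g/m^3/s).
#' @export
exchange_terms <- function(c, Sl, k, wet = TRUE, gamma = 1) {
  if (any(c(k$k01, k$k10) < 0)) stop("kinetic constants must be >= 0")
  out <- gamma * (-k$k01 * c + k$k10 * Sl)
  out * (wet * 1)
}

# Static transport topology for a grid: interior mask (active cells that are
# not tide-boundary cells), tide-adjacency of faces, and the boundary-face
# lists used for the export/import ledger. Wet gating happens per call in
# transport_core from the current depth field.
transport_workspace <- function(grid, params, inflow = NULL, h_dry = 0.01) {
  nx <- grid$nx; ny <- grid$ny
  ob <- grid$open_boundary
  tide <- matrix(FALSE, nx, ny)
  tb <- ob[ob$kind == "tide", , drop = FALSE]
  if (nrow(tb) > 0) tide[cbind(tb$i, tb$j)] <- TRUE
  interior <- grid$active & !tide
  tidecell <- tide

  ws <- list(nx = nx, ny = ny, dx = grid$dx, dy = grid$dy,
             Dx = params$Dx, Dy = params$Dy, c_inflow = params$c_inflow,
             interior = interior, tidecell = tidecell, inflow = inflow,
             h_dry = h_dry)
  if (!is.null(inflow)) {
    ws$infl_i <- as.integer(inflow$i - 1L)
    ws$infl_j <- as.integer(inflow$j - 1L)
    ws$infl_side <- match(inflow$side, c("N", "S", "E", "W")) - 1L
  } else {
    ws$infl_i <- integer(0); ws$infl_j <- integer(0); ws$infl_side <- integer(0)
  }

  ia <- 1:(nx - 1); ib <- 2:nx
  intL <- interior[ia, , drop = FALSE]; intR <- interior[ib, , drop = FALSE]
  ws$pairx_int <- intL & intR
  ws$bndx <- xor(intL, intR) &
    (tide[ia, , drop = FALSE] | tide[ib, , drop = FALSE])
  ws$intL <- intL
  bx <- which(ws$bndx, arr.ind = TRUE)
  if (nrow(bx) > 0) {
    sgn <- ifelse(tide[cbind(bx[, 1] + 1, bx[, 2])], 1, -1) # outward sign
    ws$bfx_idx <- cbind(bx[, 1] + 1, bx[, 2])
    ws$bfx_sign <- sgn
  }
  if (ny >= 2) {
    ja <- 1:(ny - 1); jb <- 2:ny
    intB <- interior[, ja, drop = FALSE]; intT <- interior[, jb, drop = FALSE]
    ws$pairy_int <- intB & intT
    ws$bndy <- xor(intB, intT) &
      (tide[, ja, drop = FALSE] | tide[, jb, drop = FALSE])
    ws$intB <- intB
    by <- which(ws$bndy, arr.ind = TRUE)
    if (nrow(by) > 0) {
      sgn <- ifelse(tide[cbind(by[, 1], by[, 2] + 1)], 1, -1)
      ws$bfy_idx <- cbind(by[, 1], by[, 2] + 1)
      ws$bfy_sign <- sgn
    }
  }
  if (!is.null(inflow)) {
    for (r in seq_len(nrow(inflow))) {
      i <- inflow$i[r]; j <- inflow$j[r]
      if (inflow$side[r] == "N") {
        ws$bfy_idx <- rbind(ws$bfy_idx, c(i, j + 1)); ws$bfy_sign <- c(ws$bfy_sign, 1)
      } else if (inflow$side[r] == "S") {
        ws$bfy_idx <- rbind(ws$bfy_idx, c(i, 1)); ws$bfy_sign <- c(ws$bfy_sign, -1)
      } else if (inflow$side[r] == "E") {
        ws$bfx_idx <- rbind(ws$bfx_idx, c(i + 1, j)); ws$bfx_sign <- c(ws$bfx_sign, 1)
      } else {
        ws$bfx_idx <- rbind(ws$bfx_idx, c(1, j)); ws$bfx_sign <- c(ws$bfx_sign, -1)
      }
    }
  }
  ws
}

# Kernel dispatcher: compiled core by default, vectorized R reference kernel
# for cross-checks.
transport_core <- function(m, h0, qx, qy, dt, ws, core = c("cpp", "r")) {
  core <- match.arg(core)
  if (core == "r") return(transport_core_r(m, h0, qx, qy, dt, ws))
  transport_core_cpp(m, h0, qx, qy, dt, ws$interior, ws$tidecell,
                     ws$Dx, ws$Dy, ws$c_inflow, ws$h_dry, ws$dx, ws$dy,
                     ws$infl_i, ws$infl_j, ws$infl_side)
}

# Finite-volume advection-dispersion update of areal mass m = c * h (g/m^2);
# R reference kernel.
#
# m      : areal Cr mass field at interval start
# h0     : depth field at interval start (consistent with qx, qy)
# qx, qy : mean face volume fluxes per unit width (m^2/s) over the interval
# dt     : interval length (s)
# Advective face mass flux is upwind; dispersion is central across wet
# interior face pairs. Outgoing fluxes are limited per cell so the update
# preserves nonnegativity without losing conservation. Returns
# list(m, exported, imported) with boundary masses in g.
transport_core_r <- function(m, h0, qx, qy, dt, ws) {
  nx <- ws$nx; ny <- ws$ny; dx <- ws$dx; dy <- ws$dy
  interior <- ws$interior
  cc <- m / pmax(h0, 1e-12)
  cc[!interior] <- 0
  cbnd <- ws$c_inflow
  hd <- ws$h_dry

  ia <- 1:(nx - 1); ib <- 2:nx
  cL <- cc[ia, , drop = FALSE]; cR <- cc[ib, , drop = FALSE]
  q <- qx[ib, , drop = FALSE]
  pos <- (q > 0)
  # upwind concentration; non-interior upwind cells contribute the boundary value
  upL <- ws$intL * cL + (!ws$intL) * cbnd
  intR2 <- ws$interior[ib, , drop = FALSE]
  upR <- intR2 * cR + (!intR2) * cbnd
  cup <- pos * upL + (!pos) * upR
  fa <- q * cup * (ws$pairx_int | ws$bndx)
  wpx <- ws$pairx_int & (h0[ia, , drop = FALSE] > hd) & (h0[ib, , drop = FALSE] > hd)
  hfx <- 0.5 * (h0[ia, , drop = FALSE] + h0[ib, , drop = FALSE])
  fd <- -ws$Dx * hfx * (cR - cL) / dx * wpx
  Fx <- matrix(0, nx + 1, ny)
  Fx[ib, ] <- fa + fd

  Fy <- matrix(0, nx, ny + 1)
  if (ny >= 2) {
    ja <- 1:(ny - 1); jb <- 2:ny
    cB <- cc[, ja, drop = FALSE]; cT <- cc[, jb, drop = FALSE]
    qv <- qy[, jb, drop = FALSE]
    posv <- (qv > 0)
    upB <- ws$intB * cB + (!ws$intB) * cbnd
    intT2 <- ws$interior[, jb, drop = FALSE]
    upT <- intT2 * cT + (!intT2) * cbnd
    cupv <- posv * upB + (!posv) * upT
    fav <- qv * cupv * (ws$pairy_int | ws$bndy)
    wpy <- ws$pairy_int & (h0[, ja, drop = FALSE] > hd) & (h0[, jb, drop = FALSE] > hd)
    hfy <- 0.5 * (h0[, ja, drop = FALSE] + h0[, jb, drop = FALSE])
    fdv <- -ws$Dy * hfy * (cT - cB) / dy * wpy
    Fy[, jb] <- fav + fdv
  }

  # inflow boundary faces: prescribed discharge enters with cbnd
  inf <- ws$inflow
  if (!is.null(inf)) {
    for (r in seq_len(nrow(inf))) {
      i <- inf$i[r]; j <- inf$j[r]
      if (inf$side[r] == "N") {
        Fy[i, j + 1] <- qy[i, j + 1] * if (qy[i, j + 1] < 0) cbnd else cc[i, j]
      } else if (inf$side[r] == "S") {
        Fy[i, 1] <- qy[i, 1] * if (qy[i, 1] > 0) cbnd else cc[i, j]
      } else if (inf$side[r] == "E") {
        Fx[i + 1, j] <- qx[i + 1, j] * if (qx[i + 1, j] < 0) cbnd else cc[i, j]
      } else {
        Fx[1, j] <- qx[1, j] * if (qx[1, j] > 0) cbnd else cc[i, j]
      }
    }
  }

  # mass-positivity limiter: outgoing mass of a cell over dt cannot exceed
  # what the cell holds; all outgoing faces of a cell share its factor, so
  # face fluxes stay single-valued and conservation is untouched.
  outx_p <- pmax(Fx[2:(nx + 1), , drop = FALSE], 0)
  outx_m <- pmax(-Fx[1:nx, , drop = FALSE], 0)
  outy_p <- pmax(Fy[, 2:(ny + 1), drop = FALSE], 0)
  outy_m <- pmax(-Fy[, 1:ny, drop = FALSE], 0)
  out <- (outx_p + outx_m) / dx + (outy_p + outy_m) / dy
  need <- (out * dt > m) & interior & (out > 0)
  if (any(need)) {
    s <- matrix(1, nx, ny)
    s[need] <- m[need] / (out[need] * dt)
    fx_in <- Fx[ib, , drop = FALSE]
    sx <- (fx_in > 0) * s[ia, , drop = FALSE] + (fx_in <= 0) * s[ib, , drop = FALSE]
    Fx[ib, ] <- fx_in * sx
    if (ny >= 2) {
      jb <- 2:ny; ja <- 1:(ny - 1)
      fy_in <- Fy[, jb, drop = FALSE]
      sy <- (fy_in > 0) * s[, ja, drop = FALSE] + (fy_in <= 0) * s[, jb, drop = FALSE]
      Fy[, jb] <- fy_in * sy
    }
  }

  div <- (Fx[2:(nx + 1), , drop = FALSE] - Fx[1:nx, , drop = FALSE]) / dx +
         (Fy[, 2:(ny + 1), drop = FALSE] - Fy[, 1:ny, drop = FALSE]) / dy
  m_new <- m - dt * div
  m_new[!interior] <- 0

  exported <- 0; imported <- 0
  if (!is.null(ws$bfx_idx)) {
    fl <- Fx[ws$bfx_idx] * ws$bfx_sign * dy * dt
    exported <- exported + sum(pmax(fl, 0))
    imported <- imported + sum(pmax(-fl, 0))
  }
  if (!is.null(ws$bfy_idx)) {
    fl <- Fy[ws$bfy_idx] * ws$bfy_sign * dx * dt
    exported <- exported + sum(pmax(fl, 0))
    imported <- imported + sum(pmax(-fl, 0))
  }

  bad <- m_new < 0
  if (any(bad)) {
    if (min(m_new) < -1e-9 * max(m, 1)) {
      stop("transport produced negative mass: stability bound violated")
    }
    m_new[bad] <- 0
  }
  list(m = m_new, exported = exported, imported = imported)
}

#' Advance the dissolved-Cr field one transport step
#'
#' Finite-volume update of the depth-integrated Cr mass: upwind advection by
#' the face volume fluxes of the hydrodynamic step, central dispersion across
#' wet interior faces, point sources, and (optionally) the soil exchange
#' term. Open-boundary condition: water leaving the domain exports interior
#' concentration (zero-gradient); entering water carries `params$c_inflow`.
#' Nonnegativity is preserved.
#'
#' @param state A [transport_state()].
#' @param hydro The [hydro_state()] AFTER the matching [step_hydro()] call
#'   (its `qx`/`qy` attributes are that step's face fluxes).
#' @param hydro_prev The `hydro_state` before that step.
#' @param grid A [make_grid()] object.
#' @param params A [transport_params()].
#' @param dt Time step (s), equal to the hydrodynamic step.
#' @param sources List of [discharge_source()]s (applied after the flux
#'   update).
#' @param k Optional [kinetic_params()] for the exchange term.
#' @param Sl Soil liquid pool field (mg/kg), required with `k`.
#' @param context A [soil_context()] for the unit conversion.
#' @param h_dry Drying threshold (m).
#' @return Updated `transport_state`; attributes `exported`, `imported`,
#'   `mass_added` (g) report the step's boundary and source ledger.
#' @export
step_transport <- function(state, hydro, hydro_prev, grid, params, dt,
                           sources = list(), k = NULL, Sl = NULL,
                           context = soil_context(), h_dry = 0.01) {
  qx <- attr(hydro, "qx"); qy <- attr(hydro, "qy")
  if (is.null(qx)) stop("hydro must carry the step fluxes (qx/qy attributes)")
  h0 <- pmax(grid$bed_depth + hydro_prev$zeta, 0)
  h1 <- pmax(grid$bed_depth + hydro$zeta, 0)
  wet0 <- wet_mask(grid, hydro_prev$zeta, h_dry)

  if (any(wet0)) {
    cfl <- max(abs(qx) / grid$dx, abs(qy) / grid$dy) * dt / max(h_dry, min(h0[wet0]))
    if (is.finite(cfl) && cfl > 1 + 1e-9) {
      stop("transport step violates the advective CFL bound")
    }
  }
  ddt <- min(grid$dx^2, grid$dy^2) / (4 * max(params$Dx, params$Dy, 1e-12))
  if (dt > ddt) stop("transport step violates the dispersive stability bound")

  ws <- transport_workspace(grid, params, h_dry = h_dry)
  m <- state$c * h0
  out <- transport_core(m, h0, qx, qy, dt, ws)

  wet1 <- wet_mask(grid, hydro$zeta, h_dry)
  cnew <- out$m / pmax(h1, h_dry)
  cnew[!wet1] <- 0
  res <- transport_state(grid, cnew, state$t + dt)
  res <- apply_sources(res, sources, state$t, dt, grid, h1, h_dry)

  if (!is.null(k) && !is.null(Sl)) {
    gam <- gamma_factor(context, h1)
    ex <- exchange_terms(res$c, Sl, k, wet1, gam)
    res$c <- pmax(res$c + dt * ex, 0)
  }
  attr(res, "exported") <- out$exported
  attr(res, "imported") <- out$imported
  res
}
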