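#' Kinetic rate constants of the water-soil-plant compartment model
#'
#' First-order transfer coefficients (per second) of the linear compartment
#' model: water to soil liquid (`k01`), soil liquid back to water (`k10`),
#' sorption soil liquid to soil solid (`k12`), desorption (`k21`) and plant
#' uptake from the soil liquid (`k13`). Plant uptake depends on mangrove age:
#' `k13_young = 7e-8` per s is the greenhouse-estimated value for young
#' trees; mature forest takes up roughly an order of magnitude less
#' (`k13_mature = 7e-9` per s, a tunable placeholder - see [tune_k13()]).
#' The other defaults are order-of-magnitude placeholders normally replaced
#' by fitted values ([fit_compartment_params()]).
#'
#' @param k01,k10,k12,k21 Transfer coefficients (1/s, >= 0).
#' @param k13_young,k13_mature Plant uptake coefficients per age class
#'   (1/s, >= 0); cells without mangroves carry k13 = 0.
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(k01 = 1e-6, k10 = 1e-8, k12 = 1e-6, k21 = 1e-7,
                           k13_young = 7e-8, k13_mature = 7e-9) {
  ks <- c(k01 = k01, k10 = k10, k12 = k12, k21 = k21,
          k13_young = k13_young, k13_mature = k13_mature)
  if (any(ks < 0)) stop("kinetic constants must be >= 0")
  structure(as.list(ks), class = "kinetic_params")
}

#' Soil and plant conversion constants
#'
#' Constants that close the mass balance between concentration pools (mg/kg)
#' and per-cell chromium masses. The soil column of one cell holds
#' `rho_b * zs * dx * dy` kg of soil; all three pools (soil liquid, soil
#' solid, plant) are carried per kg of that soil column, so the areal Cr
#' mass of a pool is `pool * rho_b * zs * dx * dy * 1e-6` kg. The plant
#' biomass density `B` re-expresses the plant pool per kg of biomass
#' (`Pl_biomass = Pl * rho_b * zs / B`) for reporting.
#'
#' @param bulk_density Soil bulk density rho_b (kg/m^3).
#' @param active_layer_depth Exchanging soil layer thickness zs (m).
#' @param plant_biomass_density Above+below ground biomass B (kg/m^2).
#' @return Object of class `soil_context`.
#' @export
soil_context <- function(bulk_density = 1300, active_layer_depth = 0.3,
                         plant_biomass_density = 10) {
  if (any(c(bulk_density, active_layer_depth, plant_biomass_density) <= 0)) {
    stop("soil context constants must be positive")
  }
  structure(list(bulk_density = bulk_density,
                 active_layer_depth = active_layer_depth,
                 plant_biomass_density = plant_biomass_density),
            class = "soil_context")
}

#' Soil-to-water exchange conversion factor
#'
#' `gamma = rho_b * zs / (1000 * h)`: converts a pool rate (mg/kg of soil per
#' second) into the matching water concentration rate (g/m^3 per second) over
#' a water column of depth `h`, so that the water column loses exactly the
#' mass the soil column gains and vice versa.
#'
#' @param context A [soil_context()].
#' @param h Total water depth (m), vectorized.
#' @return Dimensionless conversion factor(s).
#' @export
gamma_factor <- function(context, h) {
  context$bulk_density * context$active_layer_depth / (1000 * pmax(h, 1e-12))
}

#' Compartment pools
#'
#' Cr content of the soil liquid (`Sl`), soil solid (`Ss`) and plant (`Pl`)
#' pools, mg/kg of soil column, per cell.
#'
#' @param Sl,Ss,Pl Pool fields (matrices or scalars), >= 0.
#' @param nx,ny Dimensions when scalars are given.
#' @return Object of class `compartment_state`.
#' @export
compartment_state <- function(Sl = 0, Ss = 0, Pl = 0, nx = NULL, ny = NULL) {
  if (is.matrix(Sl)) { nx <- nrow(Sl); ny <- ncol(Sl) }
  if (is.null(nx)) { nx <- 1; ny <- 1 }
  expand <- function(x) if (is.matrix(x)) x else matrix(x, nx, ny)
  Sl <- expand(Sl); Ss <- expand(Ss); Pl <- expand(Pl)
  if (any(Sl < 0) || any(Ss < 0) || any(Pl < 0)) stop("pools must be >= 0")
  structure(list(Sl = Sl, Ss = Ss, Pl = Pl), class = "compartment_state")
}

#' Right-hand side of the compartment mass balances
#'
#' Linear kinetics
#' \deqn{dSl/dt = k01 c - (k12 + k13 + k10) Sl + k21 Ss}
#' \deqn{dSs/dt = k12 Sl - k21 Ss}
#' \deqn{dPl/dt = k13 Sl}
#' plus the matching water-side source/sink
#' `water_exchange = gamma * (-k01 c + k10 Sl)` (g/m^3/s). With the
#' conversion factor `gamma` from [gamma_factor()] the water column loses
#' exactly the mass the pools gain.
#'
#' @param c Water concentration (g/m^3), scalar or field.
#' @param state A [compartment_state()].
#' @param k A [kinetic_params()].
#' @param k13 Plant uptake coefficient (1/s), scalar or per-cell field;
#'   defaults to the young-tree value in `k`.
#' @param gamma Soil-to-water conversion factor (default 1; see
#'   [gamma_factor()]).
#' @return List with fields `dSl`, `dSs`, `dPl` (mg/kg/s) and
#'   `water_exchange` (g/m^3/s).
#' @export
compartment_rhs <- function(c, state, k, k13 = k$k13_young, gamma = 1) {
  dSl <- k$k01 * c - (k$k12 + k13 + k$k10) * state$Sl + k$k21 * state$Ss
  dSs <- k$k12 * state$Sl - k$k21 * state$Ss
  dPl <- k13 * state$Sl
  list(dSl = dSl, dSs = dSs, dPl = dPl,
       water_exchange = gamma * (-k$k01 * c + k$k10 * state$Sl))
}

# Homogeneous rate matrix of the pool system for one k13 value.
compartment_matrix <- function(k, k13) {
  matrix(c(-(k$k12 + k13 + k$k10), k$k12, k13,
           k$k21, -k$k21, 0,
           0, 0, 0), 3, 3)
}

# Matrix exponential for the small (<= 4 x 4) rate matrices: scaling and
# squaring with a Taylor core (norm scaled below 1/2, 13 terms reach full
# double precision). Dedicated implementation because the propagator sits in
# the parameter-estimation inner loop.
expm_small <- function(M) {
  n <- nrow(M)
  nrm <- max(colSums(abs(M)))
  j <- if (nrm > 0.5) ceiling(log2(nrm)) + 1L else 0L
  A <- M / 2^j
  E <- diag(n); term <- diag(n)
  for (i in 1:13) {
    term <- term %*% A / i
    E <- E + term
  }
  for (i in seq_len(j)) E <- E %*% E
  E
}

# Exact propagator over dt for frozen water concentration:
#   pools(t+dt) = P %*% pools(t) + q * c
# computed from the matrix exponential of the augmented 4x4 system.
compartment_propagator <- function(k, k13, dt) {
  A <- compartment_matrix(k, k13)
  M <- rbind(cbind(A, c(k$k01, 0, 0)), 0)
  E <- expm_small(M * dt)
  list(P = E[1:3, 1:3], q = E[1:3, 4])
}

#' Closed-form solution of the compartment model under constant water
#' concentration
#'
#' Exact solution of the linear pool system for `c` held constant, via the
#' matrix exponential of the augmented rate matrix. Serves as the oracle the
#' numerical integrators are verified against.
#'
#' @param k A [kinetic_params()].
#' @param c_const Constant water concentration (g/m^3).
#' @param t Time(s) since the initial state (s); vectorized.
#' @param initial A [compartment_state()] (any shape; typically 1 x 1).
#' @param k13 Plant uptake coefficient (default young-tree value).
#' @return For scalar `t`, a `compartment_state`; for vector `t`, a data
#'   frame with columns `t`, `Sl`, `Ss`, `Pl` (single-cell initial state
#'   only).
#' @export
analytic_compartments <- function(k, c_const, t, initial = compartment_state(),
                                  k13 = k$k13_young) {
  solve_one <- function(tt) {
    pr <- compartment_propagator(k, k13, tt)
    list(Sl = pr$P[1, 1] * initial$Sl + pr$P[1, 2] * initial$Ss +
           pr$P[1, 3] * initial$Pl + pr$q[1] * c_const,
         Ss = pr$P[2, 1] * initial$Sl + pr$P[2, 2] * initial$Ss +
           pr$P[2, 3] * initial$Pl + pr$q[2] * c_const,
         Pl = pr$P[3, 1] * initial$Sl + pr$P[3, 2] * initial$Ss +
           pr$P[3, 3] * initial$Pl + pr$q[3] * c_const)
  }
  if (length(t) == 1) {
    s <- solve_one(t)
    return(compartment_state(s$Sl, s$Ss, s$Pl))
  }
  if (length(initial$Sl) != 1) stop("vector t requires a single-cell initial state")
  out <- lapply(t, solve_one)
  data.frame(t = t,
             Sl = vapply(out, function(s) s$Sl[1], numeric(1)),
             Ss = vapply(out, function(s) s$Ss[1], numeric(1)),
             Pl = vapply(out, function(s) s$Pl[1], numeric(1)))
}

#' Advance the compartment pools one step
#'
#' Updates the pools over `dt` with the water concentration frozen, on wet
#' cells only (dry cells are inert: no exchange, no internal kinetics).
#' The default integrator is the exact per-cell propagator (unconditionally
#' stable); `"rk4"` (classical Runge-Kutta with `substeps` sub-intervals) and
#' `"euler"` are available as independent numerical routes.
#'
#' The returned `dc` is the water-concentration change that balances the pool
#' mass change exactly: `dc = -gamma * (dSl + dSs + dPl)`.
#'
#' @param state A [compartment_state()].
#' @param c Water concentration field (g/m^3).
#' @param k A [kinetic_params()].
#' @param dt Time step (s).
#' @param wet Logical field of wet cells (default all wet).
#' @param k13 Plant uptake coefficient, scalar or per-cell field.
#' @param gamma Soil-to-water conversion factor field (see [gamma_factor()]).
#' @param method `"exact"`, `"rk4"` or `"euler"`.
#' @param substeps Sub-intervals for the numerical methods.
#' @return List with the updated `state` and the water change field `dc`
#'   (g/m^3).
#' @export
step_compartments <- function(state, c, k, dt, wet = TRUE,
                              k13 = k$k13_young, gamma = 1,
                              method = c("exact", "rk4", "euler"),
                              substeps = 1) {
  method <- match.arg(method)
  Sl <- state$Sl; Ss <- state$Ss; Pl <- state$Pl
  if (length(c) == 1) c <- array(c, dim = dim(Sl))
  if (length(wet) == 1) wet <- array(wet, dim = dim(Sl))
  if (length(k13) == 1) k13 <- array(k13, dim = dim(Sl))

  if (method == "exact") {
    # one propagator per distinct (k13, always-same dt) value
    vals <- unique(k13[wet])
    Sl2 <- Sl; Ss2 <- Ss; Pl2 <- Pl
    for (kv in vals) {
      sel <- wet & (k13 == kv)
      pr <- compartment_propagator(k, kv, dt)
      Sl2[sel] <- pr$P[1, 1] * Sl[sel] + pr$P[1, 2] * Ss[sel] + pr$q[1] * c[sel]
      Ss2[sel] <- pr$P[2, 1] * Sl[sel] + pr$P[2, 2] * Ss[sel] + pr$q[2] * c[sel]
      Pl2[sel] <- pr$P[3, 1] * Sl[sel] + pr$P[3, 2] * Ss[sel] + Pl[sel] + pr$q[3] * c[sel]
    }
    Sl <- Sl2; Ss <- Ss2; Pl <- Pl2
  } else {
    n <- max(1L, as.integer(substeps))
    h <- dt / n
    if (method == "euler") {
      stiff <- (k$k01 + k$k10 + k$k12 + k$k21 + max(k13)) * h
      if (stiff >= 1) stop("explicit Euler unstable: decrease dt or raise substeps")
    }
    deriv <- function(Sl, Ss, Pl) {
      list(dSl = k$k01 * c - (k$k12 + k13 + k$k10) * Sl + k$k21 * Ss,
           dSs = k$k12 * Sl - k$k21 * Ss,
           dPl = k13 * Sl)
    }
    for (s in seq_len(n)) {
      if (method == "euler") {
        d1 <- deriv(Sl, Ss, Pl)
        dSl <- d1$dSl * h; dSs <- d1$dSs * h; dPl <- d1$dPl * h
      } else {
        d1 <- deriv(Sl, Ss, Pl)
        d2 <- deriv(Sl + 0.5 * h * d1$dSl, Ss + 0.5 * h * d1$dSs, Pl + 0.5 * h * d1$dPl)
        d3 <- deriv(Sl + 0.5 * h * d2$dSl, Ss + 0.5 * h * d2$dSs, Pl + 0.5 * h * d2$dPl)
        d4 <- deriv(Sl + h * d3$dSl, Ss + h * d3$dSs, Pl + h * d3$dPl)
        dSl <- h / 6 * (d1$dSl + 2 * d2$dSl + 2 * d3$dSl + d4$dSl)
        dSs <- h / 6 * (d1$dSs + 2 * d2$dSs + 2 * d3$dSs + d4$dSs)
        dPl <- h / 6 * (d1$dPl + 2 * d2$dPl + 2 * d3$dPl + d4$dPl)
      }
      Sl <- ifelse(wet, Sl + dSl, Sl)
      Ss <- ifelse(wet, Ss + dSs, Ss)
      Pl <- ifelse(wet, Pl + dPl, Pl)
    }
  }

  dtot <- (Sl - state$Sl) + (Ss - state$Ss) + (Pl - state$Pl)
  dc <- -gamma * dtot
  out <- state
  out$Sl <- Sl; out$Ss <- Ss; out$Pl <- Pl
  list(state = out, dc = dc)
}

#' Plant uptake rate field over a time window
#'
#' Average plant uptake rate `(Pl_end - Pl_start) / days` per cell
#' (mg/kg/day) between the two saved pool snapshots bracketing the window.
#'
#' @param run A [run_simulation()] result containing `Pl` snapshots.
#' @param window Numeric length-2 vector `(t_start, t_end)` in seconds.
#' @return `nx` x `ny` matrix of uptake rates (mg/kg/day), >= 0.
#' @export
uptake_rate_field <- function(run, window) {
  tt <- run$snapshot_times
  if (window[2] <= window[1]) stop("window end must exceed window start")
  if (window[1] < min(tt) - 1e-9 || window[2] > max(tt) + 1e-9) {
    stop("window outside the run's snapshot range")
  }
  i0 <- max(which(tt <= window[1] + 1e-9))
  i1 <- min(which(tt >= window[2] - 1e-9))
  days <- (tt[i1] - tt[i0]) / 86400
  (run$snapshots$Pl[[i1]] - run$snapshots$Pl[[i0]]) / days
}
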