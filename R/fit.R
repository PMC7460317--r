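#' Estimate kinetic constants from greenhouse time series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the closed-form compartment trajectories
#' ([analytic_compartments()]) against observed pool series, fitted jointly
#' over all observed pools. Each pool's residuals are weighted by the inverse
#' standard deviation of its observed series so that mg/L water
#' concentrations and mg/kg pools contribute on comparable scales.
#'
#' @param data Observations: `data.frame(time, pool, value)` with `pool` in
#'   `"Sl"`, `"Ss"`, `"Pl"` (times in seconds), or a
#'   [make_greenhouse_dataset()] object (then `c0` and `initial` are taken
#'   from it).
#' @param c0 Constant water concentration during the experiment (g/m^3).
#' @param initial Initial [compartment_state()] (single cell).
#' @param start Named starting values for
#'   `k01, k10, k12, k21, k13` (1/s). Default: the [kinetic_params()]
#'   defaults with the young-tree `k13 = 7e-8`.
#' @param free Names of the parameters to estimate; the others stay fixed at
#'   `start`.
#' @param lower,upper Box bounds for the free parameters (recycled).
#' @param ftol,ptol Convergence tolerances on cost and parameters.
#' @return Object of class `fit_result`: `estimates` (all five constants),
#'   `rss`, `ci` (95% intervals from the fit curvature, free parameters),
#'   `converged`, `identifiable`, `message`.
#' @export
fit_compartment_params <- function(data, c0 = NULL, initial = NULL,
                                   start = NULL, free = NULL,
                                   lower = 0, upper = Inf,
                                   ftol = 1e-10, ptol = 1e-8) {
  if (inherits(data, "greenhouse_dataset")) {
    if (is.null(c0)) c0 <- data$c0
    if (is.null(initial)) initial <- data$initial
    data <- data$observations
  }
  if (is.null(initial)) initial <- compartment_state()
  stopifnot(all(c("time", "pool", "value") %in% names(data)))
  if (!all(data$pool %in% c("Sl", "Ss", "Pl"))) {
    stop("pool must be one of 'Sl', 'Ss', 'Pl'")
  }
  if (any(data$value < 0)) stop("observations must be nonnegative")
  obs <- data[data$time > 0, , drop = FALSE] # t = 0 repeats the initial state
  if (length(unique(obs$time)) < 1 || nrow(obs) < 1) {
    stop("need observations at (at least) one positive time")
  }

  defaults <- kinetic_params()
  if (is.null(start)) {
    start <- c(k01 = defaults$k01, k10 = defaults$k10, k12 = defaults$k12,
               k21 = defaults$k21, k13 = defaults$k13_young)
  }
  pnames <- c("k01", "k10", "k12", "k21", "k13")
  stopifnot(all(pnames %in% names(start)))
  if (is.null(free)) free <- pnames
  stopifnot(all(free %in% pnames))
  if (nrow(obs) < length(free)) {
    stop(sprintf(
      "identifiability: %d observations cannot determine %d free parameters",
      nrow(obs), length(free)))
  }

  wts <- numeric(nrow(obs))
  for (p in unique(obs$pool)) {
    sel <- obs$pool == p
    s <- stats::sd(obs$value[sel])
    if (!is.finite(s) || s == 0) s <- max(abs(obs$value[sel]), 1)
    wts[sel] <- 1 / s
  }

  predict_obs <- function(par_full) {
    k <- kinetic_params(k01 = par_full["k01"], k10 = par_full["k10"],
                        k12 = par_full["k12"], k21 = par_full["k21"],
                        k13_young = par_full["k13"])
    traj <- analytic_compartments(k, c0, unique(obs$time), initial,
                                  k13 = par_full["k13"])
    traj <- as.data.frame(traj)
    idx <- match(obs$time, traj$t)
    vapply(seq_len(nrow(obs)),
           function(r) traj[idx[r], obs$pool[r]], numeric(1))
  }
  residual_fn <- function(par_free) {
    par_full <- start
    par_full[free] <- par_free
    wts * (obs$value - predict_obs(par_full))
  }

  # sensitivity rank check at the starting point
  J0 <- numeric_jacobian(residual_fn, start[free])
  sv <- svd(J0)$d
  identifiable <- length(sv) > 0 && min(sv) > 1e-8 * max(sv, 1e-300)
  if (!identifiable) {
    warning("parameters not identifiable from these observations: ",
            "the sensitivity matrix is rank deficient")
  }

  fit <- minpack.lm::nls.lm(
    par = start[free], lower = rep_len(lower, length(free)),
    upper = rep_len(upper, length(free)), fn = residual_fn,
    control = minpack.lm::nls.lm.control(ftol = ftol, ptol = ptol,
                                         maxiter = 500))
  est_full <- start
  est_full[free] <- fit$par

  rss <- sum(fit$fvec^2)
  n <- nrow(obs); p <- length(free)
  ci <- matrix(NA_real_, p, 2, dimnames = list(free, c("lower", "upper")))
  if (identifiable && n > p) {
    Jh <- numeric_jacobian(residual_fn, fit$par)
    JtJ <- crossprod(Jh)
    covm <- tryCatch(solve(JtJ) * rss / (n - p), error = function(e) NULL)
    if (!is.null(covm)) {
      se <- sqrt(pmax(diag(covm), 0))
      ci[, 1] <- pmax(fit$par - 1.96 * se, 0)
      ci[, 2] <- fit$par + 1.96 * se
    }
  }

  structure(list(estimates = est_full, rss = rss, ci = ci,
                 converged = fit$info %in% 1:4, identifiable = identifiable,
                 message = fit$message),
            class = "fit_result")
}

numeric_jacobian <- function(fn, par, rel = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (i in seq_along(par)) {
    h <- max(abs(par[i]) * rel, 1e-14)
    pp <- par; pp[i] <- pp[i] + h
    J[, i] <- (fn(pp) - f0) / h
  }
  J
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", if (x$converged) "converged" else "NOT converged",
      if (!x$identifiable) "(rank-deficient sensitivities)", "\n")
  est <- data.frame(estimate = x$estimates)
  rownames(est) <- names(x$estimates)
  if (!is.null(x$ci) && nrow(x$ci) > 0) {
    est$lower <- NA_real_; est$upper <- NA_real_
    est[rownames(x$ci), c("lower", "upper")] <- x$ci
  }
  print(signif(as.matrix(est), 4))
  cat(sprintf("residual sum of squares: %.6g\n", x$rss))
  invisible(x)
}

#' Tune the mature-forest uptake coefficient against field plant data
#'
#' 1-D bounded minimization (golden section via [stats::optimize()]) of the
#' RMSE between an observed plant-pool series and the series a scenario
#' runner produces for a candidate `k13`. The bracket ends are also
#' evaluated; if a bracket end wins (monotone objective, no interior
#' minimum), it is returned with a warning.
#'
#' @param field_obs Observed plant concentrations ([station_series()] or
#'   numeric vector).
#' @param runner Function `k13 -> simulated series` aligned with `field_obs`.
#' @param bracket Length-2 search interval for `k13` (1/s).
#' @param tol Relative convergence tolerance.
#' @return List with `k13`, `rmse`, `boundary` (TRUE if a bracket end won).
#' @export
tune_k13 <- function(field_obs, runner, bracket = c(1e-10, 7e-8), tol = 1e-4) {
  if (length(bracket) != 2 || bracket[2] <= bracket[1]) {
    stop("bracket must be an increasing length-2 interval")
  }
  obj <- function(k13) rmse(field_obs, runner(k13))
  opt <- stats::optimize(obj, interval = bracket, tol = tol * diff(bracket))
  cand <- c(opt$minimum, bracket)
  vals <- c(opt$objective, obj(bracket[1]), obj(bracket[2]))
  best <- which.min(vals)
  boundary <- best != 1
  if (boundary) {
    warning("no interior minimum in the bracket; returning the boundary value")
  }
  list(k13 = cand[best], rmse = vals[best], boundary = boundary)
}

#' Write a fit report
#'
#' CSV of the estimated constants with confidence bounds, plus a plain-text
#' summary with the skill metrics of the fitted trajectories against the
#' observations they were fitted to.
#'
#' @param fit A [fit_compartment_params()] result.
#' @param data The observations the fit used (`data.frame(time, pool, value)`
#'   or a [make_greenhouse_dataset()] object).
#' @param c0,initial Experiment constants as in [fit_compartment_params()].
#' @param path Output CSV path; the text summary goes to `<path>.txt`.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, data, c0 = NULL, initial = NULL, path) {
  if (inherits(data, "greenhouse_dataset")) {
    if (is.null(c0)) c0 <- data$c0
    if (is.null(initial)) initial <- data$initial
    data <- data$observations
  }
  if (is.null(initial)) initial <- compartment_state()
  est <- fit$estimates
  df <- data.frame(parameter = names(est), estimate = unname(est),
                   lower = NA_real_, upper = NA_real_)
  if (!is.null(fit$ci) && nrow(fit$ci) > 0) {
    idx <- match(rownames(fit$ci), df$parameter)
    df$lower[idx] <- fit$ci[, 1]; df$upper[idx] <- fit$ci[, 2]
  }
  utils::write.csv(df, path, row.names = FALSE)

  k <- kinetic_params(k01 = est["k01"], k10 = est["k10"], k12 = est["k12"],
                      k21 = est["k21"], k13_young = est["k13"])
  obs <- data[data$time > 0, , drop = FALSE]
  traj <- analytic_compartments(k, c0, unique(obs$time), initial,
                                k13 = est["k13"])
  idx <- match(obs$time, traj$t)
  pred <- vapply(seq_len(nrow(obs)),
                 function(r) traj[idx[r], obs$pool[r]], numeric(1))
  lines <- c(
    sprintf("fit %s (%s)", if (fit$converged) "converged" else "NOT converged",
            fit$message),
    sprintf("residual sum of squares: %.6g", fit$rss),
    sprintf("RMSE:  %.6g", rmse(obs$value, pred)),
    if (stats::sd(obs$value) > 0) c(
      sprintf("NSE:   %.6g", nse(obs$value, pred)),
      sprintf("d:     %.6g", index_of_agreement(obs$value, pred))
    )
  )
  writeLines(lines, paste0(path, ".txt"))
  invisible(path)
}
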