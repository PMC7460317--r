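#' Station time series
#'
#' A labelled time series of observed or simulated values at a station.
#'
#' @param times Strictly increasing times (s).
#' @param values Values (units as labelled), same length as `times`.
#' @param label Series label.
#' @return Object of class `station_series`.
#' @export
station_series <- function(times, values, label = "") {
  if (length(times) != length(values)) stop("times and values must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label),
            class = "station_series")
}

align_series <- function(obs, sim) {
  ov <- if (inherits(obs, "station_series")) obs$values else as.numeric(obs)
  sv <- if (inherits(sim, "station_series")) sim$values else as.numeric(sim)
  if (length(ov) != length(sv)) stop("observed and simulated series must be aligned (equal length)")
  if (inherits(obs, "station_series") && inherits(sim, "station_series") &&
      length(obs$times) == length(sim$times) &&
      any(abs(obs$times - sim$times) > 1e-6 * max(1, abs(obs$times)))) {
    stop("observed and simulated series are sampled at different times")
  }
  list(obs = ov, sim = sv)
}

#' Nash-Sutcliffe model efficiency
#'
#' `NSE = 1 - sum((obs - sim)^2) / sum((obs - mean(obs))^2)`. 1 is a perfect
#' match; 0 means the model is only as accurate as the observed mean;
#' negative values mean the mean outperforms the model. Unbounded below,
#' at most 1.
#'
#' @param obs,sim Aligned series ([station_series()] or numeric vectors),
#'   length >= 2; `obs` must not be constant.
#' @return Efficiency value.
#' @export
nse <- function(obs, sim) {
  s <- align_series(obs, sim)
  if (length(s$obs) < 2) stop("need at least two points")
  denom <- sum((s$obs - mean(s$obs))^2)
  if (denom == 0) stop("NSE undefined: observed series is constant (zero variance)")
  1 - sum((s$obs - s$sim)^2) / denom
}

#' Willmott index of agreement
#'
#' `d = 1 - sum((obs - sim)^2) / sum((|sim - mean(obs)| + |obs - mean(obs)|)^2)`,
#' bounded in `[0, 1]`; 1 is a perfect match, 0 no agreement. The potential
#' error in the denominator uses the observed mean in both absolute terms
#' (Willmott's classical form). A zero denominator can only occur when both
#' series are identically the observed mean, a perfect match: 1 is returned
#' by convention.
#'
#' @param obs,sim Aligned series, length >= 2.
#' @return Agreement value in `[0, 1]`.
#' @export
index_of_agreement <- function(obs, sim) {
  s <- align_series(obs, sim)
  if (length(s$obs) < 2) stop("need at least two points")
  mo <- mean(s$obs)
  denom <- sum((abs(s$sim - mo) + abs(s$obs - mo))^2)
  if (denom == 0) return(1)
  1 - sum((s$obs - s$sim)^2) / denom
}

#' Root mean square error
#'
#' `RMSE = sqrt(mean((obs - sim)^2))`, in the units of the series; 0 is a
#' perfect fit.
#'
#' @param obs,sim Aligned series.
#' @return Error value (>= 0).
#' @export
rmse <- function(obs, sim) {
  s <- align_series(obs, sim)
  if (length(s$obs) == 0) stop("empty series")
  sqrt(mean((s$obs - s$sim)^2))
}
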