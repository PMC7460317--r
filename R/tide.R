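#' Harmonic tidal boundary
#'
#' Open-boundary water level synthesized from a sum of harmonic constituents,
#' `zeta(t) = mean_level + sum_k A_k cos(2 pi t / T_k - phi_k)`. The default
#' is a single semidiurnal constituent of 2.7 m amplitude, the average tidal
#' amplitude of the estuary the toy domains emulate.
#'
#' An optional smooth start-up ramp (sin^2 over `ramp` seconds) is available
#' to suppress free seiche modes when spinning a frictionless channel up from
#' rest; it defaults to 0 (no ramp).
#'
#' @param amplitude Amplitudes A_k in metres (>= 0).
#' @param period Periods T_k in seconds (> 0). Default: M2 semidiurnal,
#'   12.42 h.
#' @param phase Phases phi_k in radians.
#' @param mean_level Datum offset in metres.
#' @param ramp Ramp-up time in seconds (>= 0).
#' @return Object of class `tide_boundary`.
#' @export
tide_boundary <- function(amplitude = 2.7, period = 12.42 * 3600,
                          phase = 0, mean_level = 0, ramp = 0) {
  n <- max(length(amplitude), length(period), length(phase))
  amplitude <- rep_len(amplitude, n)
  period <- rep_len(period, n)
  phase <- rep_len(phase, n)
  if (any(amplitude < 0)) stop("amplitudes must be >= 0")
  if (any(period <= 0)) stop("periods must be positive")
  if (ramp < 0) stop("ramp must be >= 0")
  structure(list(amplitude = amplitude, period = period, phase = phase,
                 mean_level = mean_level, ramp = ramp),
            class = "tide_boundary")
}

#' Tidal water level at a time
#'
#' Evaluates the harmonic synthesis of a [tide_boundary()] at time `t`
#' (vectorized over `t`).
#'
#' @param boundary A [tide_boundary()].
#' @param t Time(s) in seconds.
#' @return Water level(s) in metres above datum.
#' @export
tide_elevation <- function(boundary, t) {
  stopifnot(inherits(boundary, "tide_boundary"))
  z <- vapply(t, function(tt) {
    sum(boundary$amplitude * cos(2 * pi * tt / boundary$period - boundary$phase))
  }, numeric(1))
  if (boundary$ramp > 0) {
    f <- pmin(1, pmax(0, t / boundary$ramp))
    z <- z * sin(0.5 * pi * f)^2
  }
  boundary$mean_level + z
}
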