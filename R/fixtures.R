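#' Idealized rectangular tidal channel
#'
#' Deterministic generator for solver verification domains: a straight
#' channel of uniform depth and riverbed land type, with each end either
#' closed, tidal (Dirichlet elevation from `tide`) or an inflow boundary.
#' Closing both ends yields a volume-conserving basin for seiche tests.
#'
#' @param length Channel length (m), along x.
#' @param width Channel width (m), along y.
#' @param depth Uniform bed depth below datum (m).
#' @param resolution Cell size (m); must divide `length` and `width`.
#' @param tide A [tide_boundary()] (default: one semidiurnal constituent of
#'   2.7 m amplitude).
#' @param west,east Boundary kind at the x = 0 / x = length end:
#'   `"tide"`, `"closed"` or `"inflow"`.
#' @return List with `grid` ([make_grid()]) and `tide`.
#' @export
make_tidal_channel <- function(length = 10000, width = 500, depth = 10,
                               resolution = 100, tide = tide_boundary(),
                               west = c("tide", "closed", "inflow"),
                               east = c("closed", "tide", "inflow")) {
  west <- match.arg(west); east <- match.arg(east)
  if (length <= 0 || width <= 0 || depth <= 0) stop("degenerate channel dimensions")
  nx <- length / resolution; ny <- width / resolution
  if (nx != round(nx) || ny != round(ny)) {
    stop("resolution must divide length and width")
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  ob <- data.frame(i = integer(), j = integer(), kind = character())
  if (west != "closed") {
    ob <- rbind(ob, data.frame(i = 1L, j = seq_len(ny),
                               kind = if (west == "tide") "tide" else "inflow"))
  }
  if (east != "closed") {
    ob <- rbind(ob, data.frame(i = nx, j = seq_len(ny),
                               kind = if (east == "tide") "tide" else "inflow"))
  }
  grid <- make_grid(nx, ny, resolution, resolution,
                    bed_depth = depth, landtype = "riverbed",
                    open_boundary = ob)
  list(grid = grid, tide = tide)
}

#' Toy two-bank estuary catchment
#'
#' Deterministic desk-scale domain emulating the study setting: a straight
#' tidal channel running south-north, a mangrove floodplain on the west bank,
#' bare industrial land on the east bank, semidiurnal tide entering from the
#' south, limited freshwater inflow from the north, and the five industrial
#' point sources of the default source table discharging into the channel
#' along the east bank. Also carries the station registry (M1 downstream,
#' M5 upstream) and the constructed-wetland template used by scenario SC3.
#'
#' All elements are deterministic functions of the arguments (no randomness).
#'
#' @param channel_length Channel length (m), along y (northward = upstream).
#' @param channel_width Channel width (m).
#' @param floodplain_width Width of each bank's floodplain (m).
#' @param depth Channel bed depth below datum (m).
#' @param floodplain_elevation Bank elevation above datum (m); banks flood
#'   when the tide exceeds it.
#' @param resolution Cell size (m).
#' @param tide_amplitude Semidiurnal amplitude (m); default 2.7 m, the
#'   average tidal amplitude of the emulated estuary. The phase is chosen so
#'   the simulation starts at rising mid-tide (no initial jump).
#' @param discharge Upstream freshwater inflow (m^3/s); default the dry
#'   season average 580 m^3/s.
#' @param source_rates Named Cr discharge rates (mg/s) of the five industrial
#'   sources.
#' @param wetland_tau Residence time of each constructed-wetland unit (s).
#' @param wetland_depth Water depth of the wetland units (m).
#' @return Object of class `toy_catchment`: list with `grid`, `tide`,
#'   `discharge`, `sources`, `stations`, `wetland_template`, and the
#'   resolved geometry in `spec`.
#' @export
make_toy_catchment <- function(channel_length = 10000, channel_width = 400,
                               floodplain_width = 800, depth = 10,
                               floodplain_elevation = 0.5, resolution = 100,
                               tide_amplitude = 2.7, discharge = 580,
                               source_rates = c(A2 = 0.5, A1 = 1,
                                                Cai_Mep = 1, Phu_My = 0.2,
                                                Go_Dau = 2),
                               wetland_tau = 86400, wetland_depth = 0.5) {
  ny <- channel_length / resolution
  nw <- floodplain_width / resolution
  nc <- channel_width / resolution
  if (any(c(ny, nw, nc) != round(c(ny, nw, nc))) || nc < 1 || nw < 1) {
    stop("resolution must divide the channel and floodplain dimensions")
  }
  ny <- as.integer(ny); nw <- as.integer(nw); nc <- as.integer(nc)
  nx <- 2L * nw + nc
  west_cols <- seq_len(nw)                 # mangrove floodplain (west bank)
  chan_cols <- seq(nw + 1L, nw + nc)       # riverbed
  east_cols <- seq(nw + nc + 1L, nx)       # bare industrial land (east bank)

  landtype <- matrix("bare", nx, ny)
  landtype[west_cols, ] <- "mangrove_floodplain"
  landtype[chan_cols, ] <- "riverbed"
  bed <- matrix(-floodplain_elevation, nx, ny)
  bed[chan_cols, ] <- depth

  ob <- rbind(
    data.frame(i = chan_cols, j = 1L, kind = "tide"),
    data.frame(i = chan_cols, j = ny, kind = "inflow")
  )
  grid <- make_grid(nx, ny, resolution, resolution, bed_depth = bed,
                    landtype = landtype, open_boundary = ob)

  tide <- tide_boundary(amplitude = tide_amplitude, phase = pi / 2)

  # sources sit in the channel cell adjacent to the east bank, ordered
  # upstream (Go Dau) to downstream (Cai Mep) as in the emulated estuary
  iq <- chan_cols[nc]
  jpos <- round(ny * c(A2 = 0.60, A1 = 0.70, Cai_Mep = 0.35,
                       Phu_My = 0.45, Go_Dau = 0.82))
  nm <- names(source_rates)
  stopifnot(!is.null(nm), all(nm %in% names(jpos)))
  sources <- lapply(nm, function(s) {
    discharge_source(name = s, i = iq, j = jpos[[s]], rate = source_rates[[s]])
  })

  stations <- data.frame(
    name = c("M1", "M5"),
    i = chan_cols[ceiling(nc / 2)],
    j = as.integer(round(ny * c(0.15, 0.85)))
  )

  # SC3 wetland template: one unit per source, a strip of east-bank cells
  # (2 cells wide, 3 cells long) directly behind the discharge point
  strip_cols <- east_cols[seq_len(min(2L, length(east_cols)))]
  wetland_template <- lapply(seq_along(sources), function(ii) {
    s <- sources[[ii]]
    jj <- pmin(pmax(s$j + (-1:1), 1L), ny)
    cells <- as.matrix(expand.grid(i = strip_cols, j = jj))
    list(id = ii, source = s$name, cells = cells,
         tau = wetland_tau, depth = wetland_depth)
  })

  structure(list(grid = grid, tide = tide, discharge = discharge,
                 sources = sources, stations = stations,
                 wetland_template = wetland_template,
                 spec = list(channel_length = channel_length,
                             channel_width = channel_width,
                             floodplain_width = floodplain_width,
                             depth = depth,
                             floodplain_elevation = floodplain_elevation,
                             resolution = resolution,
                             tide_amplitude = tide_amplitude,
                             discharge = discharge)),
            class = "toy_catchment")
}

#' Synthetic greenhouse phytoremediation dataset
#'
#' Samples the closed-form compartment trajectories
#' ([analytic_compartments()]) under a constant water concentration at the
#' experiment's sampling design (start, month three, month six by default)
#' and perturbs them with multiplicative Gaussian noise. Identical seeds give
#' identical datasets; the noiseless version equals the analytic solution
#' exactly.
#'
#' @param k_true A [kinetic_params()]; the young-tree `k13` applies.
#' @param c0 Constant water concentration during the experiment (g/m^3).
#' @param times Sampling times (s); default 0, 3 and 6 months (30-day
#'   months).
#' @param noise_sd Relative (multiplicative) noise standard deviation, >= 0.
#' @param seed Integer seed for the dataset's private RNG stream.
#' @param initial Initial [compartment_state()] (single cell).
#' @return Object of class `greenhouse_dataset`: `observations`
#'   (`data.frame(time, pool, value)`), `truth` (named vector of the five
#'   constants), `c0`, `initial`, `noise_sd`, `seed`.
#' @export
make_greenhouse_dataset <- function(k_true = kinetic_params(), c0 = 500,
                                    times = c(0, 3, 6) * 30 * 86400,
                                    noise_sd = 0, seed = 1,
                                    initial = compartment_state()) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  traj <- analytic_compartments(k_true, c0, times, initial,
                                k13 = k_true$k13_young)
  obs <- data.frame(
    time = rep(times, 3),
    pool = rep(c("Sl", "Ss", "Pl"), each = length(times)),
    value = c(traj$Sl, traj$Ss, traj$Pl)
  )
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    obs$value <- pmax(obs$value * (1 + stats::rnorm(nrow(obs), 0, noise_sd)), 0)
  }
  structure(list(observations = obs,
                 truth = c(k01 = k_true$k01, k10 = k_true$k10,
                           k12 = k_true$k12, k21 = k_true$k21,
                           k13 = k_true$k13_young),
                 c0 = c0, initial = initial, times = times,
                 noise_sd = noise_sd, seed = seed),
            class = "greenhouse_dataset")
}
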