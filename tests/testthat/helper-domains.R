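# Small domains shared across tests. Everything is built in code.

# closed rectangular basin for conservation/seiche checks
basin_grid <- function(nx = 50, ny = 3, depth = 10, res = 100) {
  make_tidal_channel(nx * res, ny * res, depth, res,
                     west = "closed", east = "closed")$grid
}

# coarse toy catchment (10 x 50 cells) for fast scenario tests
small_catchment <- function(...) {
  make_toy_catchment(channel_length = 10000, channel_width = 400,
                     floodplain_width = 800, resolution = 200, ...)
}

# advance a hydro state n steps, returning the final state and fluxes
run_hydro <- function(grid, state, params, boundary = NULL, dt, n,
                      discharge = 0, each = NULL) {
  ws <- mangroveCr:::hydro_workspace(grid, params, boundary, discharge)
  zeta <- state$zeta; u <- state$u; v <- state$v
  for (s in seq_len(n)) {
    o <- mangroveCr:::hydro_step_core(zeta, u, v, (s - 1) * dt, dt, ws)
    zeta <- o$zeta; u <- o$u; v <- o$v
    if (!is.null(each)) each(s, zeta, u, v)
  }
  list(zeta = zeta, u = u, v = v, qx = o$qx, qy = o$qy)
}
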