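#' Land-type labels
#'
#' The four land classes the simulator distinguishes. Roughness and plant
#' uptake are tied to the class: the riverbed is smooth unvegetated channel,
#' the mangrove floodplain carries a mature forest, constructed wetlands are
#' engineered basins planted with young mangroves, and bare cells are
#' unvegetated ground (mudflat, cleared land, industrial surfaces).
#'
#' @format Character vector of the four admissible labels.
#' @export
LAND_TYPES <- c("riverbed", "mangrove_floodplain", "constructed_wetland", "bare")

#' Default Manning roughness per land type
#'
#' Calibrated channel and floodplain values: 0.005 s m^-1/3 for the riverbed
#' and 0.15 s m^-1/3 for the mangrove floodplain. Constructed wetlands are
#' vegetated like the floodplain (0.15); bare ground defaults to 0.025,
#' smoother than forest but rougher than the dredged channel. All values are
#' configurable through `manning_for_landtype()`.
#'
#' @format Named numeric vector (s m^-1/3), one entry per land type.
#' @export
MANNING_DEFAULTS <- c(
  riverbed = 0.005,
  mangrove_floodplain = 0.15,
  constructed_wetland = 0.15,
  bare = 0.025
)

#' Manning roughness for a land-type label
#'
#' Maps land-type labels to Manning roughness coefficients. The enumeration
#' is closed: any label outside [LAND_TYPES] is rejected by name.
#'
#' @param landtype Character vector of land-type labels.
#' @param values Named numeric vector of per-class roughness
#'   (s m^-1/3); defaults to [MANNING_DEFAULTS]. Must cover all four classes
#'   with positive values.
#' @return Numeric vector of roughness values, same length as `landtype`.
#' @examples
#' manning_for_landtype("riverbed")             # 0.005
#' manning_for_landtype("mangrove_floodplain")  # 0.15
#' @export
manning_for_landtype <- function(landtype, values = MANNING_DEFAULTS) {
  if (!all(LAND_TYPES %in% names(values))) {
    stop("`values` must name all land types: ", paste(LAND_TYPES, collapse = ", "))
  }
  if (any(values[LAND_TYPES] <= 0)) stop("Manning roughness must be positive")
  bad <- setdiff(unique(landtype), LAND_TYPES)
  if (length(bad) > 0) {
    stop("unknown land type label(s): ", paste(shQuote(bad), collapse = ", "))
  }
  unname(values[landtype])
}

#' Construct a structured model grid
#'
#' Builds the static domain shared by the hydrodynamic, transport and
#' compartment solvers: a Cartesian grid of `nx` x `ny` cells (cell-centered
#' scalars, 1-based indices, x increasing eastward, y northward) carrying bed
#' depth, land classification, Manning roughness and the active/open-boundary
#' topology.
#'
#' Bed depth `d` is positive downward from the reference datum, so total
#' water depth is `h = d + zeta`; land above datum carries negative `d`.
#'
#' @param nx,ny Cell counts (>= 1).
#' @param dx,dy Cell sizes in metres (> 0).
#' @param bed_depth `nx` x `ny` matrix of bed depth below datum (m, positive
#'   down), or a single number recycled to the whole domain.
#' @param landtype `nx` x `ny` character matrix of labels from [LAND_TYPES],
#'   or a single label.
#' @param active Logical `nx` x `ny` matrix of domain membership (default all
#'   active).
#' @param open_boundary `data.frame(i, j, kind)` of open-boundary cells;
#'   `kind` is `"tide"` or `"inflow"`. Every open-boundary cell must be
#'   active and lie on the domain edge.
#' @param manning_values Per-class roughness passed to
#'   [manning_for_landtype()].
#' @return An object of class `cr_grid`: list with fields `nx, ny, dx, dy,
#'   bed_depth, landtype, manning, active, open_boundary`.
#' @export
make_grid <- function(nx, ny, dx, dy, bed_depth, landtype,
                      active = NULL, open_boundary = NULL,
                      manning_values = MANNING_DEFAULTS) {
  if (length(nx) != 1 || length(ny) != 1 || nx < 1 || ny < 1 ||
      nx != round(nx) || ny != round(ny)) {
    stop("nx and ny must be integers >= 1")
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (!(dx > 0) || !(dy > 0)) stop("dx and dy must be positive")

  as_field <- function(x, what, mode = "numeric") {
    if (length(x) == 1) x <- matrix(x, nx, ny)
    if (!is.matrix(x) || nrow(x) != nx || ncol(x) != ny) {
      stop(sprintf("%s must be a %d x %d matrix", what, nx, ny))
    }
    storage_ok <- switch(mode,
      numeric = is.numeric(x), character = is.character(x), logical = is.logical(x))
    if (!storage_ok) stop(sprintf("%s must be %s", what, mode))
    x
  }
  bed_depth <- as_field(bed_depth, "bed_depth")
  landtype <- as_field(landtype, "landtype", "character")
  active <- if (is.null(active)) matrix(TRUE, nx, ny) else as_field(active, "active", "logical")

  manning <- matrix(manning_for_landtype(as.vector(landtype), manning_values), nx, ny)
  if (any(manning[active] <= 0)) stop("Manning roughness must be positive on active cells")

  if (is.null(open_boundary)) {
    open_boundary <- data.frame(i = integer(), j = integer(), kind = character())
  }
  stopifnot(all(c("i", "j", "kind") %in% names(open_boundary)))
  if (nrow(open_boundary) > 0) {
    ob <- open_boundary
    if (any(ob$i < 1 | ob$i > nx | ob$j < 1 | ob$j > ny)) {
      stop("open-boundary cell outside the grid")
    }
    if (!all(ob$kind %in% c("tide", "inflow"))) stop("open-boundary kind must be 'tide' or 'inflow'")
    idx <- cbind(ob$i, ob$j)
    if (!all(active[idx])) stop("every open-boundary cell must be active")
    on_edge <- ob$i == 1 | ob$i == nx | ob$j == 1 | ob$j == ny
    if (!all(on_edge)) stop("every open-boundary cell must lie on the domain edge")
  }

  structure(
    list(nx = nx, ny = ny, dx = dx, dy = dy,
         bed_depth = bed_depth, landtype = landtype, manning = manning,
         active = active, open_boundary = open_boundary),
    class = "cr_grid"
  )
}

#' @export
print.cr_grid <- function(x, ...) {
  cat(sprintf("<cr_grid> %d x %d cells (%.0f m x %.0f m), %d active\n",
              x$nx, x$ny, x$dx, x$dy, sum(x$active)))
  tab <- table(x$landtype[x$active])
  cat("  land types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (nrow(x$open_boundary) > 0) {
    tb <- table(x$open_boundary$kind)
    cat("  open boundary:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Wet-cell mask for a surface-elevation field
#'
#' A cell is wet iff it is active and its total depth `h = d + zeta` exceeds
#' the drying threshold. Monotone in `zeta`: raising the surface everywhere
#' never dries a wet cell.
#'
#' @param grid A [make_grid()] object.
#' @param zeta Surface elevation field (m above datum), `nx` x `ny` matrix or
#'   scalar.
#' @param h_dry Drying threshold in metres (> 0), default 0.01.
#' @return Logical `nx` x `ny` matrix.
#' @export
wet_mask <- function(grid, zeta, h_dry = 0.01) {
  if (!(h_dry > 0)) stop("h_dry must be positive")
  if (length(zeta) == 1) zeta <- matrix(zeta, grid$nx, grid$ny)
  grid$active & (grid$bed_depth + zeta > h_dry)
}

#' Cell indices of a land type
#' @param grid A [make_grid()] object.
#' @param landtype A label from [LAND_TYPES].
#' @return Two-column matrix of (i, j) indices.
#' @export
cells_of_landtype <- function(grid, landtype) {
  stopifnot(landtype %in% LAND_TYPES)
  which(grid$landtype == landtype, arr.ind = TRUE)
}
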