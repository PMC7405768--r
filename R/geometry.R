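#' Define a grid of orientation hypercolumns
#'
#' Lays out `n_rows` x `n_cols` hypercolumns (HCs), each a 0.5 x 0.5 mm patch
#' of cortex corresponding to (0.25 deg)^2 of visual field at 2 mm/deg
#' magnification.  Each HC is divided into six 60-degree wedges around its
#' pinwheel centre; going counterclockwise the wedges carry the intended
#' orientations 0, 30, 60, 90, 120, 150 degrees (0 = vertical).
#'
#' @param n_rows,n_cols number of HC rows/columns (>= 1).
#' @return an object of class `hc_grid`: fields `n_rows`, `n_cols`,
#'   `hc_side` (um), `deg_per_hc`, `pinwheel_centers` (matrix of um
#'   coordinates, one row per HC, row-major order), `wedge_angles` (degrees).
#' @examples
#' g <- hc_grid(3, 3)
#' nrow(g$pinwheel_centers)  # 9
#' @export
hc_grid <- function(n_rows = 3L, n_cols = 3L) {
  if (n_rows < 1 || n_cols < 1)
    stop_config("hc_grid: n_rows and n_cols must be >= 1 (got %s x %s)",
                n_rows, n_cols)
  ij <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  centers <- cbind(x = (ij$col - 0.5) * HC_SIDE_UM,
                   y = (ij$row - 0.5) * HC_SIDE_UM)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 hc_side = HC_SIDE_UM, deg_per_hc = DEG_PER_HC,
                 pinwheel_centers = centers,
                 wedge_angles = seq(0, 150, by = 30)),
            class = "hc_grid")
}

#' @export
print.hc_grid <- function(x, ...) {
  cat(sprintf("<hc_grid> %d x %d hypercolumns (%.0f um side, %.2f deg/HC)\n",
              x$n_rows, x$n_cols, x$hc_side, x$deg_per_hc))
  invisible(x)
}

# HC index (row-major, 1-based) of cortical positions in um.
hc_index <- function(grid, x_um, y_um) {
  col <- pmin(pmax(floor(x_um / grid$hc_side), 0), grid$n_cols - 1)
  row <- pmin(pmax(floor(y_um / grid$hc_side), 0), grid$n_rows - 1)
  as.integer(row * grid$n_cols + col + 1L)
}

# Wedge index (1..6, counterclockwise from the positive x axis) around the
# pinwheel centre of the neuron's own HC.
wedge_index <- function(grid, x_um, y_um, hc) {
  cx <- grid$pinwheel_centers[hc, 1]
  cy <- grid$pinwheel_centers[hc, 2]
  ang <- atan2(y_um - cy, x_um - cx) %% (2 * pi)
  as.integer(pmin(floor(ang / (pi / 3)), 5)) + 1L
}

#' Populate the cortical sheet with E and I neurons
#'
#' Distributes neurons uniformly over the sheet at a density of (by default)
#' 4000 neurons per hypercolumn, three quarters excitatory, and assigns each
#' neuron its HC and intended orientation domain (pinwheel wedge).  The E:I
#' ratio is exactly 3:1 (counts rounded consistently: the inhibitory count is
#' `round(N/4)` and the excitatory count three times that).
#'
#' @param grid an [hc_grid()].
#' @param density neurons per hypercolumn (default 4000).
#' @param seed integer seed; the sheet is bit-reproducible given the seed.
#' @return a `data.frame` (the neuron table) with columns `id`, `x_um`,
#'   `y_um`, `cls` ("E"/"I"), `hc`, `wedge`, `domain_deg`, `x_deg`, `y_deg`.
#' @examples
#' nt <- build_sheet(hc_grid(1, 1), seed = 1)
#' table(nt$cls)  # 3000 E, 1000 I
#' @export
build_sheet <- function(grid, density = 4000, seed = 1L) {
  if (!inherits(grid, "hc_grid")) stop_config("build_sheet: grid must be an hc_grid")
  if (density <= 0) stop_config("build_sheet: density must be positive")
  n_hc <- grid$n_rows * grid$n_cols
  n_i <- round(density * n_hc / 4)
  n_e <- 3L * n_i
  n <- n_e + n_i
  with_seed(seed, {
    x <- runif(n, 0, grid$n_cols * grid$hc_side)
    y <- runif(n, 0, grid$n_rows * grid$hc_side)
  })
  cls <- rep(c("E", "I"), c(n_e, n_i))
  hc <- hc_index(grid, x, y)
  wg <- wedge_index(grid, x, y, hc)
  data.frame(id = seq_len(n), x_um = x, y_um = y, cls = cls,
             hc = hc, wedge = wg,
             domain_deg = grid$wedge_angles[wg],
             x_deg = x / UM_PER_DEG, y_deg = y / UM_PER_DEG)
}

# Logical mask of neurons at least `margin_um` from every sheet edge.
interior_mask <- function(grid, x_um, y_um, margin_um) {
  w <- grid$n_cols * grid$hc_side
  h <- grid$n_rows * grid$hc_side
  x_um >= margin_um & x_um <= w - margin_um &
    y_um >= margin_um & y_um <= h - margin_um
}
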