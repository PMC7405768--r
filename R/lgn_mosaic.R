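#' Build the jittered ON/OFF magnocellular LGN mosaic
#'
#' ON receptive-field centres start on a regular triangular lattice with
#' 0.125 deg spacing; OFF centres sit at the barycentres of the
#' upward-pointing lattice triangles (one per lattice point, so ON and OFF
#' densities are equal and one (0.25 deg)^2 hypercolumn region contains about
#' 10 cells, roughly 5 ON and 5 OFF).  Every point is then perturbed by an
#' independent 2-D Gaussian jitter, emulating the irregularity of real
#' magnocellular retinal ganglion cell mosaics.
#'
#' @param extent_deg numeric length-4 `c(xmin, xmax, ymin, ymax)` in visual
#'   degrees, or length-2 `c(width, height)` anchored at the origin.  Must
#'   cover at least one hypercolumn (0.25 deg) in each dimension.
#' @param spacing ON-ON lattice spacing in degrees (default 0.125).
#' @param jitter_sd SD of the Gaussian jitter in degrees (default 0.02,
#'   small relative to the spacing).
#' @param seed integer seed.
#' @return a `data.frame` of class `lgn_mosaic` with columns `id`,
#'   `polarity` ("ON"/"OFF"), `x_deg`, `y_deg` (jittered centres) and
#'   `base_x`, `base_y` (pre-jitter lattice positions); the call arguments
#'   are attached as attributes.
#' @examples
#' m <- build_lgn_mosaic(c(-0.25, 1.0, -0.25, 1.0), seed = 1)
#' table(m$polarity)
#' @export
build_lgn_mosaic <- function(extent_deg, spacing = 0.125, jitter_sd = 0.02,
                             seed = 1L) {
  if (spacing <= 0) stop_config("build_lgn_mosaic: spacing must be positive")
  if (length(extent_deg) == 2) extent_deg <- c(0, extent_deg[1], 0, extent_deg[2])
  if (length(extent_deg) != 4)
    stop_config("build_lgn_mosaic: extent_deg must have length 2 or 4")
  w <- extent_deg[2] - extent_deg[1]
  h <- extent_deg[4] - extent_deg[3]
  if (w < DEG_PER_HC || h < DEG_PER_HC)
    stop_config("build_lgn_mosaic: extent (%.3f x %.3f deg) smaller than one HC",
                w, h)
  a <- spacing
  rh <- a * sqrt(3) / 2                       # lattice row height
  rows <- seq(extent_deg[3] - rh, extent_deg[4] + rh, by = rh)
  pts <- do.call(rbind, lapply(seq_along(rows), function(j) {
    off <- if (j %% 2 == 0) a / 2 else 0      # staggered rows
    xs <- seq(extent_deg[1] - a + off, extent_deg[2] + a, by = a)
    cbind(xs, rows[j])
  }))
  on_base <- pts
  # barycentre of the upward triangle whose base starts at each ON point:
  # vertices (x, y), (x + a, y), (x + a/2, y + rh) -> (x + a/2, y + rh/3)
  off_base <- cbind(pts[, 1] + a / 2, pts[, 2] + rh / 3)
  base <- rbind(on_base, off_base)
  polarity <- rep(c("ON", "OFF"), each = nrow(pts))
  jit <- with_seed(seed, matrix(rnorm(2 * nrow(base), sd = jitter_sd),
                                ncol = 2))
  x <- base[, 1] + jit[, 1]
  y <- base[, 2] + jit[, 2]
  keep <- x >= extent_deg[1] & x <= extent_deg[2] &
          y >= extent_deg[3] & y <= extent_deg[4]
  out <- data.frame(id = seq_len(sum(keep)), polarity = polarity[keep],
                    x_deg = x[keep], y_deg = y[keep],
                    base_x = base[keep, 1], base_y = base[keep, 2])
  attr(out, "spacing") <- spacing
  attr(out, "jitter_sd") <- jitter_sd
  attr(out, "extent_deg") <- extent_deg
  class(out) <- c("lgn_mosaic", "data.frame")
  out
}

#' Count mosaic cells per hypercolumn region
#'
#' Counts LGN cells whose centres fall in each (0.25 deg)^2 region of a
#' rectangular grid of hypercolumn regions anchored at `origin_deg`.
#'
#' @param mosaic an [build_lgn_mosaic()] table.
#' @param n_rows,n_cols grid of HC regions to count over.
#' @param origin_deg lower-left corner of the first region.
#' @return data.frame with `row`, `col`, `n_on`, `n_off`, `n`.
#' @export
lgn_cells_per_hc <- function(mosaic, n_rows = 3L, n_cols = 3L,
                             origin_deg = c(0, 0)) {
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  res <- lapply(seq_len(nrow(grid)), function(k) {
    x0 <- origin_deg[1] + (grid$col[k] - 1) * DEG_PER_HC
    y0 <- origin_deg[2] + (grid$row[k] - 1) * DEG_PER_HC
    sel <- mosaic$x_deg >= x0 & mosaic$x_deg < x0 + DEG_PER_HC &
           mosaic$y_deg >= y0 & mosaic$y_deg < y0 + DEG_PER_HC
    c(n_on = sum(mosaic$polarity[sel] == "ON"),
      n_off = sum(mosaic$polarity[sel] == "OFF"))
  })
  res <- do.call(rbind, res)
  data.frame(row = grid$row, col = grid$col, n_on = res[, 1],
             n_off = res[, 2], n = res[, 1] + res[, 2])
}
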