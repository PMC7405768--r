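#' Place layer-6 projection units
#'
#' L6 is not modeled as a network; only the ~300 E-cells per hypercolumn
#' whose ascending axons terminate in L4 are represented, each as a spike
#' train whose rate is set on demand by the feedback rule (see
#' [l6_response()]).  Units are laid out on an even grid (20 x 15 per HC)
#' covering the sheet.
#'
#' @param grid an [hc_grid()].
#' @param units_per_hc units per hypercolumn (default 300).
#' @return data.frame with `id`, `x_um`, `y_um`.
#' @export
place_l6_units <- function(grid, units_per_hc = 300) {
  # factor units_per_hc into a near-square per-HC grid
  nx <- ceiling(sqrt(units_per_hc * 4 / 3))
  ny <- ceiling(units_per_hc / nx)
  while (nx * ny > units_per_hc && (nx - 1) * ny >= units_per_hc) nx <- nx - 1
  sx <- grid$hc_side / nx
  sy <- grid$hc_side / ny
  xs <- seq(sx / 2, grid$n_cols * grid$hc_side - sx / 2, by = sx)
  ys <- seq(sy / 2, grid$n_rows * grid$hc_side - sy / 2, by = sy)
  g <- expand.grid(x_um = xs, y_um = ys)
  data.frame(id = seq_len(nrow(g)), x_um = g$x_um, y_um = g$y_um)
}

#' Wire the L6 -> L4 projection
#'
#' Each L4 cell draws its presynaptic L6 units: E-cells have 38-55 of them,
#' anticorrelated with the cell's LGN input count (a cell with 0 LGN inputs,
#' a complex-cell seed, sits at the top of the range; one with 6 at the
#' bottom); I-cells have 100-110.  Each input is drawn, independently, from
#' the units within 180 um of the cell with probability 5/6 and from the
#' 180-360 um annulus otherwise, reflecting the measured concentration of an
#' L6 axon's synaptic contacts.
#'
#' @param neurons neuron table with `n_lgn` set (see [assign_lgn_inputs()]).
#' @param l6_units from [place_l6_units()].
#' @param seed integer seed.
#' @param e_range,i_range in-degree ranges for E and I cells.
#' @param p_near probability a contact is made within `r_near`.
#' @param r_near,r_far disk and annulus radii in um.
#' @return integer edge matrices `l6e`, `l6i` (columns `pre` = unit id,
#'   `post` = neuron id) in a named list.
#' @export
wire_l6 <- function(neurons, l6_units, seed = 1L,
                    e_range = c(38L, 55L), i_range = c(100L, 110L),
                    p_near = 5 / 6, r_near = 180, r_far = 360) {
  n_lgn <- if (is.null(neurons$n_lgn)) rep(3L, nrow(neurons)) else neurons$n_lgn
  with_seed(seed, {
    edges <- list(l6e = vector("list", 0), l6i = vector("list", 0))
    ex <- l6_units$x_um; ey <- l6_units$y_um
    pre_e <- list(); post_e <- list(); pre_i <- list(); post_i <- list()
    for (i in seq_len(nrow(neurons))) {
      if (neurons$cls[i] == "E") {
        lo <- e_range[1]; hi <- e_range[2]
        k <- round(hi - (hi - lo) * min(n_lgn[i], 6) / 6)
      } else {
        k <- sample(seq(i_range[1], i_range[2]), 1L)
      }
      d2 <- (ex - neurons$x_um[i])^2 + (ey - neurons$y_um[i])^2
      near <- which(d2 <= r_near^2)
      far <- which(d2 > r_near^2 & d2 <= r_far^2)
      n_near <- sum(runif(k) < p_near)
      # near the sheet edge one pool may run short; borrow from the other
      # so the anatomical in-degree range holds everywhere
      n_near <- min(n_near, length(near))
      n_far <- min(k - n_near, length(far))
      n_near <- min(n_near + (k - n_near - n_far), length(near))
      picks <- c(sample_units(near, n_near), sample_units(far, n_far))
      if (neurons$cls[i] == "E") {
        pre_e[[length(pre_e) + 1L]] <- picks
        post_e[[length(post_e) + 1L]] <- rep(neurons$id[i], length(picks))
      } else {
        pre_i[[length(pre_i) + 1L]] <- picks
        post_i[[length(post_i) + 1L]] <- rep(neurons$id[i], length(picks))
      }
    }
    list(l6e = cbind(pre = unlist(pre_e), post = unlist(post_e)),
         l6i = cbind(pre = unlist(pre_i), post = unlist(post_i)))
  })
}

# sample without replacement, robust to length-1 pools
sample_units <- function(pool, k) {
  if (k <= 0 || !length(pool)) return(integer(0))
  pool[sample.int(length(pool), k)]
}

#' The L6 response function f(R)
#'
#' The instantaneous firing rate of an L6 unit is a stimulus-independent
#' sigmoid of R, the recent mean firing rate of L4 neurons near the unit
#' (see [local_l4_rate()]).  Anchors follow known L6 spiking behaviour:
#' about 5 spikes/s when L4 is at its spontaneous rate and about 80 spikes/s
#' when L4 fires at peak rates.
#'
#' @param R local L4 mean rate, spikes/s (>= 0).
#' @param floor,ceiling asymptotic L6 rates (spikes/s).
#' @param midpoint,slope logistic midpoint and scale (spikes/s).
#' @return L6 rate in spikes/s.
#' @examples
#' l6_response(3.5)   # ~5 sp/s at the spontaneous L4 rate
#' l6_response(25)    # ~80 sp/s at peak L4 rates
#' @export
l6_response <- function(R, floor = 5, ceiling = 80, midpoint = 12,
                        slope = 1.8) {
  if (any(R < 0)) stop_config("l6_response: R must be nonnegative")
  floor + (ceiling - floor) / (1 + exp(-(R - midpoint) / slope))
}

#' Rate-dependent facilitation of L6 -> L4 synapses
#'
#' L6 E-cells produce larger EPSPs in L4 at higher firing rates.  The weight
#' multiplier is piecewise linear through (30 sp/s, 1.0) and (60 sp/s, 1.1)
#' -- i.e. the coupling at 60 spikes/s is 1.1 times that at 30 spikes/s --
#' with the rate clamped to [0, 90] sp/s outside the calibrated range.
#'
#' @param rate L6 firing rate, spikes/s (>= 0).
#' @return weight multiplier (0.9 at 0 sp/s up to 1.2 at >= 90 sp/s).
#' @examples
#' l6_facilitation(60) / l6_facilitation(30)  # 1.1
#' @export
l6_facilitation <- function(rate) {
  if (any(rate < 0)) stop_config("l6_facilitation: rate must be nonnegative")
  r <- pmin(pmax(rate, 0), 90)
  1 + 0.1 * (r - 30) / 30
}

#' Local L4 firing rate around a point
#'
#' Mean firing rate of the L4 neurons within `radius_um` of `center` over
#' the `window_ms` before time `t_ms`: the spike count in the disk and
#' window divided by (number of member neurons x window).  This is the
#' quantity R that drives the L6 response function.
#'
#' @param record spike record: data.frame with `neuron` and `t_ms`.
#' @param neurons neuron table (positions in um).
#' @param center numeric length-2 cortical position in um.
#' @param t_ms evaluation time (>= `window_ms`).
#' @param radius_um disk radius (default 75).
#' @param window_ms averaging window (default 50).
#' @return rate in spikes/s.
#' @export
local_l4_rate <- function(record, neurons, center, t_ms, radius_um = 75,
                          window_ms = 50) {
  if (t_ms < window_ms)
    stop_config("local_l4_rate: t_ms (%.1f) must be >= window_ms (%.1f)",
                t_ms, window_ms)
  d2 <- (neurons$x_um - center[1])^2 + (neurons$y_um - center[2])^2
  member <- neurons$id[d2 <= radius_um^2]
  if (!length(member))
    stop_config("local_l4_rate: no neurons within %.0f um of (%.0f, %.0f)",
                radius_um, center[1], center[2])
  n_sp <- sum(record$neuron %in% member &
                record$t_ms > t_ms - window_ms & record$t_ms <= t_ms)
  n_sp / (length(member) * window_ms / 1000)
}

#' Generate one interval of L6 synaptic events at frozen rates
#'
#' Reference implementation of the L6 delivery step used inside the
#' integrator: each unit emits Poisson spikes at its current rate f(R); each
#' synaptic delivery is independently dropped with the synaptic failure
#' probability (~0.5); surviving deliveries carry the facilitation
#' multiplier evaluated at the unit's rate.
#'
#' @param rates per-unit instantaneous rates f(R), spikes/s.
#' @param targets list (per unit) of postsynaptic neuron ids.
#' @param duration_ms interval length.
#' @param fail synaptic failure probability (default 0.5).
#' @param seed integer seed.
#' @return data.frame with `unit`, `t_ms`, `post`, `weight_mult` for the
#'   delivered (non-failed) events.
#' @export
l6_spike_step <- function(rates, targets, duration_ms, fail = 0.5, seed = 1L) {
  stopifnot(length(rates) == length(targets))
  with_seed(seed, {
    out <- lapply(seq_along(rates), function(u) {
      n <- rpois(1, rates[u] * duration_ms / 1000)
      if (n == 0 || !length(targets[[u]])) return(NULL)
      t_sp <- sort(runif(n, 0, duration_ms))
      ev <- expand.grid(t_ms = t_sp, post = targets[[u]])
      ev <- ev[runif(nrow(ev)) >= fail, , drop = FALSE]
      if (!nrow(ev)) return(NULL)
      data.frame(unit = u, t_ms = ev$t_ms, post = ev$post,
                 weight_mult = l6_facilitation(rates[u]))
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(unit = integer(0), t_ms = numeric(0),
                        post = integer(0), weight_mult = numeric(0))
    out
  })
}
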