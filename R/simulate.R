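#' Run a network simulation of one stimulus
#'
#' Generates LGN spike trains for the grating analytically, assembles the
#' adjacency structures, and integrates the conductance-based
#' integrate-and-fire network with all mechanisms active (unless disabled
#' in the config): I->E synaptic depression, E threshold adaptation, and the
#' self-adjusted L6 feedback loop whose unit rates track local L4 activity
#' through the sigmoidal response function.  Per-neuron mean synaptic
#' currents split by source (LGN, recurrent L4 E, L6 feedback, ambient,
#' GABA, leak) are accumulated over the recording window.
#'
#' @param network a [build_network()] result.
#' @param stimulus a [grating_spec()] (defaults to the config's stimulus).
#' @param duration_s simulated time in seconds.
#' @param seed master seed for this run (LGN spikes, ambient, failures...).
#' @param record_from_s start of the current-recording / analysis window
#'   (default: half the duration, as in the 10 s run / last 5 s convention).
#' @param weight_scales named multipliers applied to synaptic weights for
#'   knockdown experiments, e.g. `c(S_ee = 0.75)`; `l6` scales the whole
#'   feedback projection.
#' @param record_v_ids neuron ids whose membrane potential is recorded at
#'   every step (expensive; for diagnostics).
#' @return object of class `v1_simulation`: `record` (data.frame `neuron`,
#'   `t_ms`, `cls`), `currents` (per-neuron mean currents by source, s^-1),
#'   `l6_rate_trace`, `stimulus`, `duration_s`, `window_s`, `seed`,
#'   `network` (reference to the input network), `v_trace`.
#' @export
run_simulation <- function(network, stimulus = NULL, duration_s = NULL,
                           seed = 1L, record_from_s = NULL,
                           weight_scales = NULL, record_v_ids = integer(0)) {
  cfg <- network$config
  if (is.null(stimulus))
    stimulus <- do.call(grating_spec, cfg$stimulus[
      c("contrast", "orientation_deg", "sf_cpd", "tf_hz", "phase",
        "mean_luminance")])
  if (is.null(duration_s)) duration_s <- cfg$stimulus$duration_s
  if (is.null(record_from_s)) record_from_s <- duration_s / 2
  if (duration_s <= 0) stop_config("run_simulation: duration must be positive")

  dt_ms <- cfg$lif$dt_ms
  n_steps <- round(duration_s * 1000 / dt_ms)
  filter <- do.call(lgn_filter, cfg$lgn$filter)

  # --- LGN drive: analytic rates, thinned spikes, per used cell ----------
  used <- sort(unique(unlist(network$neurons$lgn_inputs)))
  times <- seq(0, by = dt_ms / 1000, length.out = n_steps)
  lgn_events <- with_seed(sub_seed(seed, "lgn_spikes"), {
    ev_step <- vector("list", length(used))
    for (k in seq_along(used)) {
      cell <- network$mosaic[match(used[k], network$mosaic$id), ]
      tr <- lgn_rate(cell, filter, stimulus, times)
      fire <- which(runif(n_steps) < tr * dt_ms / 1000)
      if (length(fire) > 1) {   # absolute refractory thinning
        keep <- c(TRUE, diff(fire) * dt_ms >= cfg$lgn$refractory_ms)
        while (!all(keep)) {
          fire <- fire[keep]
          keep <- c(TRUE, diff(fire) * dt_ms >= cfg$lgn$refractory_ms)
        }
      }
      ev_step[[k]] <- fire - 1L   # 0-based steps
    }
    ev_step
  })
  ev_cell <- rep(seq_along(used) - 1L, lengths(lgn_events))
  ev_step <- unlist(lgn_events)
  o <- order(ev_step)
  ev_step <- as.integer(ev_step[o]); ev_cell <- ev_cell[o]

  # LGN -> L4 adjacency over used cells
  post_per_cell <- vector("list", length(used))
  nl <- network$neurons$lgn_inputs
  has <- which(lengths(nl) > 0)
  pairs <- data.frame(cell = match(unlist(nl[has]), used),
                      post = rep(has, lengths(nl[has])))
  sp <- split(pairs$post, factor(pairs$cell, levels = seq_along(used)))
  lgn_csr <- make_csr(sp, length(used))

  # recurrent adjacency by presynaptic neuron (targets of both classes)
  n <- nrow(network$neurons)
  g <- network$graph
  all_pre <- c(g$ee[, "pre"], g$ei[, "pre"], g$ie[, "pre"], g$ii[, "pre"])
  all_post <- c(g$ee[, "post"], g$ei[, "post"], g$ie[, "post"], g$ii[, "post"])
  adj_csr <- make_csr(split(all_post, factor(all_pre, levels = seq_len(n))), n)

  # L6 unit -> target adjacency and neuron -> unit memberships
  nu <- nrow(network$l6_units)
  l6_pre <- c(g$l6e[, "pre"], g$l6i[, "pre"])
  l6_post <- c(g$l6e[, "post"], g$l6i[, "post"])
  l6_csr <- make_csr(split(l6_post, factor(l6_pre, levels = seq_len(nu))), nu)
  mem_pairs <- data.frame(nrn = unlist(network$l6_members),
                          unit = rep(seq_len(nu), lengths(network$l6_members)))
  mem_csr <- make_csr(split(mem_pairs$unit, factor(mem_pairs$nrn,
                                                   levels = seq_len(n))), n)

  w <- cfg$weights
  scl <- function(nm) {
    s <- if (!is.null(weight_scales) && nm %in% names(weight_scales))
      weight_scales[[nm]] else 1
    w[[nm]] * s
  }
  l6_scale <- if (!is.null(weight_scales) && "l6" %in% names(weight_scales))
    weight_scales[["l6"]] else 1

  par <- list(
    dt_ms = dt_ms, n_steps = as.integer(n_steps),
    rec_start_ms = record_from_s * 1000,
    g_leak = cfg$lif$g_leak, V_E = cfg$lif$V_E, V_I = cfg$lif$V_I,
    tau_e_ms = cfg$lif$tau_e_ms, tau_i_ms = cfg$lif$tau_i_ms,
    delay_e_ms = cfg$lif$delay_e_ms, delay_i_ms = cfg$lif$delay_i_ms,
    ref_e_ms = cfg$lif$ref_e_ms, ref_i_ms = cfg$lif$ref_i_ms,
    S_ee = scl("S_ee"), S_ie = scl("S_ie"), S_ei = scl("S_ei"),
    S_ii = scl("S_ii"), S_lgn_e = scl("S_lgn_e"), S_lgn_i = scl("S_lgn_i"),
    S_l6_e = scl("S_l6_e"), S_l6_i = scl("S_l6_i"), S_amb = scl("S_amb"),
    amb_rate_e = cfg$ambient$rate_e, amb_rate_i = cfg$ambient$rate_i,
    dep_frac = cfg$mech$depression, dep_tau_ms = cfg$mech$dep_tau_ms,
    thr_jump = cfg$mech$thr_jump, thr_tau_ms = thr_tau_ms(cfg),
    enable_depression = cfg$mech$enable_depression,
    enable_thr_adapt = cfg$mech$enable_thr_adapt,
    enable_l6 = cfg$mech$enable_l6,
    l6_floor = cfg$l6$floor, l6_ceil = cfg$l6$ceiling,
    l6_mid = cfg$l6$midpoint, l6_slope = cfg$l6$slope,
    l6_fail = cfg$l6$fail, l6_scale = l6_scale,
    l6_update_ms = cfg$l6$update_ms, l6_window_ms = cfg$l6$window_ms,
    record_currents = TRUE,
    gE_const = 0, gI_const = 0,
    v_init = 0, record_v_ids = as.integer(record_v_ids))

  is_e <- as.integer(network$neurons$cls == "E")
  res <- with_seed(sub_seed(seed, "dynamics"), {
    par$v_init <- runif(n)   # desynchronised start
    run_network_cpp(is_e, adj_csr$ptr, adj_csr$tgt,
                    ev_step, ev_cell, lgn_csr$ptr, lgn_csr$tgt,
                    l6_csr$ptr, l6_csr$tgt, mem_csr$ptr, mem_csr$tgt,
                    as.integer(lengths(network$l6_members)), par)
  })

  record <- data.frame(neuron = res$spike_neuron, t_ms = res$spike_t_ms,
                       cls = network$neurons$cls[res$spike_neuron])
  currents <- as.data.frame(res$currents)
  currents$neuron <- seq_len(n)
  structure(list(record = record, currents = currents,
                 l6_rate_trace = res$l6_rate_trace,
                 stimulus = stimulus, duration_s = duration_s,
                 window_s = c(record_from_s, duration_s),
                 seed = as.integer(seed), network = network,
                 v_trace = res$v_trace),
            class = "v1_simulation")
}

# CSR builder: list of integer target vectors (1-based) -> 0-based ptr/tgt
make_csr <- function(split_targets, n_src) {
  lens <- integer(n_src)
  lens[as.integer(names(split_targets))] <- lengths(split_targets)
  tgt <- unlist(split_targets, use.names = FALSE)
  list(ptr = c(0L, cumsum(lens)), tgt = as.integer(tgt) - 1L)
}

#' @export
print.v1_simulation <- function(x, ...) {
  n <- nrow(x$network$neurons)
  win <- diff(x$window_s)
  sel <- x$record$t_ms >= x$window_s[1] * 1000
  re <- sum(sel & x$record$cls == "E") /
    (sum(x$network$neurons$cls == "E") * win)
  ri <- sum(sel & x$record$cls == "I") /
    (sum(x$network$neurons$cls == "I") * win)
  cat(sprintf("<v1_simulation> %.1f s, c=%.2f ori=%g deg: %d spikes; mean E %.2f sp/s, I %.2f sp/s (last %.1f s)\n",
              x$duration_s, x$stimulus$contrast, x$stimulus$orientation_deg,
              nrow(x$record), re, ri, win))
  invisible(x)
}

#' One exponential-Euler step of the conductance-based IF equation
#'
#' Reference (pure R) integration step for the normalized membrane
#' equation `dv/dt = -g_leak v - g_E (v - V_E) - g_I (v - V_I)` with fixed
#' threshold 1 and reset 0.  Vectorised over neurons; conductances are held
#' by the caller.  The compiled network integrator uses the same update.
#'
#' @param state list with `v` (voltages) and optionally `g_e`, `g_i`
#'   (conductances, s^-1).
#' @param dt_ms step, ms.
#' @param g_leak,V_E,V_I membrane constants.
#' @return state with updated `v` and logical `spiked`.
#' @export
integrate_step <- function(state, dt_ms = 0.1, g_leak = 50, V_E = 14 / 3,
                           V_I = -2 / 3) {
  if (dt_ms <= 0) stop_config("integrate_step: dt must be positive")
  g_e <- state$g_e %||% 0
  g_i <- state$g_i %||% 0
  G <- g_leak + g_e + g_i
  Vinf <- (g_e * V_E + g_i * V_I) / G
  v <- Vinf + (state$v - Vinf) * exp(-G * dt_ms / 1000)
  if (any(!is.finite(v)))
    stop_config("integrate_step: non-finite membrane potential")
  spiked <- v >= 1
  v[spiked] <- 0
  state$v <- v
  state$spiked <- spiked
  state
}
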