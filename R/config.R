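#' Default model configuration
#'
#' Returns the full nested configuration of the reference model: geometry,
#' LGN mosaic and filter, wiring kernels, synaptic weights, L6 feedback,
#' cellular mechanisms, integration constants and analysis windows.  All
#' stochastic construction and simulation is reproducible from a config
#' plus a master seed.
#'
#' Scale presets: `"mini"` is a single hypercolumn for quick checks and
#' unit tests, `"reduced"` a 1 x 3 strip used for the standard emergent
#' benchmarks, `"full"` the 3 x 3 sheet (36,000 neurons).
#'
#' @param preset one of "mini", "reduced", "full" (default "reduced").
#' @return nested named list of class `v1_config`.
#' @export
default_config <- function(preset = c("reduced", "mini", "full")) {
  preset <- match.arg(preset)
  dims <- switch(preset, mini = c(1L, 1L), reduced = c(1L, 3L),
                 full = c(3L, 3L))
  cfg <- list(
    preset = preset,
    grid = list(n_rows = dims[1], n_cols = dims[2]),
    density = list(per_hc = 4000),
    kernels = list(
      peak = c(ee = 0.15, ei = 0.6, ie = 0.6, ii = 0.6),
      targets = c(ee = 200, ei = 750, ie = 100, ii = 100)),
    lgn = list(
      spacing_deg = 0.125, jitter_sd_deg = 0.02, margin_deg = 0.5,
      i_inputs = 3L, p_aligned = 0.85, max_match_deg = 0.1,
      n_input_probs = c(0.08, 0.06, 0.06, 0.10, 0.20, 0.25, 0.25),
      refractory_ms = 2,
      filter = list(center_radius_deg = 0.05, surround_radius_deg = 0.15,
                    surround_strength = 0.8, tpeak1_ms = 20, tpeak2_ms = 40,
                    lobe2_strength = 0.7, base_rate_sps = 20,
                    max_rate_sps = 105, c50 = 0.15)),
    l6 = list(
      units_per_hc = 300, e_indegree_range = c(38L, 55L),
      i_indegree_range = c(100L, 110L), p_near = 5 / 6,
      r_near_um = 180, r_far_um = 360, member_radius_um = 75,
      floor = 5, ceiling = 80, midpoint = 21.5, slope = 1.6,
      fail = 0.5, update_ms = 5, window_ms = 50,
      spont_l4_rate = 9, peak_l4_rate = 26),
    weights = list(
      S_ee = 0.028, S_ei = 0.09, S_ie = 0.0105, S_ii = 0.75 * 0.09,
      S_lgn_e = 0.13, S_lgn_i = 0.20, S_l6_e = 0.041, S_l6_i = 0.01,
      S_amb = 0.012),
    ambient = list(rate_e = 150, rate_i = 500),
    lif = list(g_leak = 50, V_E = 14 / 3, V_I = -2 / 3,
               tau_e_ms = 3, tau_i_ms = 5, delay_e_ms = 1,
               delay_i_ms = 0.5, ref_e_ms = 2, ref_i_ms = 1, dt_ms = 0.1),
    mech = list(depression = 0.12, dep_tau_ms = 20, thr_jump = 0.2,
                thr_decay_fraction = 0.9, thr_decay_ms = 10,
                enable_depression = TRUE, enable_thr_adapt = TRUE,
                enable_l6 = TRUE),
    stimulus = list(contrast = 1, orientation_deg = 0, sf_cpd = 2.5,
                    tf_hz = 4, phase = 0, mean_luminance = 1,
                    duration_s = 10),
    analysis = list(rate_window_s = c(5, 10), silent_threshold_sps = 5,
                    pixel_um = 50, map_window_s = 1))
  class(cfg) <- c("v1_config", "list")
  cfg
}

# effective threshold-adaptation time constant (ms)
thr_tau_ms <- function(cfg)
  cfg$mech$thr_decay_ms / (-log(1 - cfg$mech$thr_decay_fraction))

#' Validate a configuration
#'
#' Checks structural sanity and the physiological ranges the model is
#' calibrated for: in particular S_EE must lie in [0.02, 0.03] (the range
#' implied by 10-20 EPSPs in quick succession reaching threshold) unless
#' `allow_out_of_range` is set, and S_II is expected to be ~0.75 * S_EI
#' (electrical coupling among I-cells is absorbed into the lowered S_II).
#'
#' @param cfg a config list.
#' @param allow_out_of_range bypass the physiological range checks (used by
#'   knockdown experiments that deliberately scale weights).
#' @return the config, invisibly; errors name the offending key.
#' @export
validate_config <- function(cfg, allow_out_of_range = FALSE) {
  need <- c("grid", "density", "kernels", "lgn", "l6", "weights",
            "ambient", "lif", "mech", "stimulus", "analysis")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop_config("validate_config: missing sections: %s", toString(miss))
  unknown <- setdiff(names(cfg), c(need, "preset"))
  if (length(unknown))
    stop_config("validate_config: unknown sections: %s", toString(unknown))
  if (cfg$grid$n_rows < 1 || cfg$grid$n_cols < 1)
    stop_config("validate_config: grid.n_rows / grid.n_cols must be >= 1")
  if (cfg$density$per_hc <= 0)
    stop_config("validate_config: density.per_hc must be positive")
  if (!allow_out_of_range) {
    if (cfg$weights$S_ee < 0.02 || cfg$weights$S_ee > 0.03)
      stop_config("validate_config: weights.S_ee = %g outside the calibrated range [0.02, 0.03]",
                  cfg$weights$S_ee)
    if (abs(cfg$weights$S_ii - 0.75 * cfg$weights$S_ei) > 1e-6 * cfg$weights$S_ei)
      stop_config("validate_config: weights.S_ii should equal 0.75 * S_ei")
  }
  if (cfg$stimulus$contrast < 0 || cfg$stimulus$contrast > 1)
    stop_config("validate_config: stimulus.contrast must be in [0, 1]")
  invisible(cfg)
}

#' Load a configuration from a YAML file
#'
#' Reads a (possibly partial) config, fills in defaults from
#' [default_config()] of the named preset, validates, and attaches a
#' content hash for provenance.
#'
#' @param path YAML file path.
#' @param allow_out_of_range see [validate_config()].
#' @return validated `v1_config` with attribute `hash`.
#' @export
load_config <- function(path, allow_out_of_range = FALSE) {
  if (!file.exists(path)) stop_config("load_config: no such file: %s", path)
  user <- yaml::read_yaml(path)
  preset <- if (!is.null(user$preset)) user$preset else "reduced"
  cfg <- merge_config(default_config(preset), user)
  validate_config(cfg, allow_out_of_range)
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Save a configuration to YAML
#' @param cfg a config list.
#' @param path output file.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# recursive overlay of user values onto defaults; unknown keys error
merge_config <- function(base, user, prefix = "") {
  for (k in names(user)) {
    key <- paste0(prefix, k)
    if (!k %in% names(base) && prefix != "")
      stop_config("config: unknown key '%s'", key)
    if (is.list(base[[k]]) && is.list(user[[k]]) && !is.null(names(base[[k]])))
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(key, "."))
    else base[[k]] <- user[[k]]
  }
  base
}

#' Stable content hash of a configuration
#' @param cfg a config list.
#' @return character scalar.
#' @export
config_hash <- function(cfg) {
  # canonicalise through YAML so a save/load round trip hashes identically
  s <- yaml::as.yaml(yaml::yaml.load(yaml::as.yaml(unclass(cfg))))
  # polynomial rolling hash over the canonical text; stable across sessions
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' @export
print.v1_config <- function(x, ...) {
  cat(sprintf("<v1_config> preset=%s  grid=%dx%d HC  S_EE=%g\n",
              x$preset %||% "?", x$grid$n_rows, x$grid$n_cols,
              x$weights$S_ee))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
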