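#' Deterministic test and benchmark fixtures
#'
#' Three reference fixtures used throughout the test-suite and examples:
#' `"unit"` is a hand-wired 20-neuron toy (15 E, 5 I, enumerated edges, no
#' LGN/L6) for exact bookkeeping checks; `"mini"` a 1-HC network (4,000
#' neurons); `"reduced"` the 1 x 3 HC strip used for the emergent
#' benchmarks.  The same kind and seed always return the identical fixture.
#'
#' @param kind "unit", "mini" or "reduced".
#' @param seed master seed (default 42).
#' @return a `v1_network` (the unit fixture has empty mosaic/L6 slots).
#' @export
make_fixture <- function(kind = c("unit", "mini", "reduced"), seed = 42L) {
  kind <- match.arg(kind)
  if (kind == "unit") return(unit_fixture(seed))
  build_network(default_config(kind), seed = seed)
}

# 20 neurons on a 4 x 5 grid, ring-ish enumerated wiring
unit_fixture <- function(seed) {
  grid <- hc_grid(1, 1)
  pos <- expand.grid(x_um = seq(50, 450, by = 100),
                     y_um = seq(62.5, 437.5, by = 125))
  neurons <- data.frame(id = 1:20, x_um = pos$x_um, y_um = pos$y_um,
                        cls = rep(c("E", "E", "E", "I"), 5),
                        hc = 1L, wedge = 1L, domain_deg = 0,
                        x_deg = pos$x_um / UM_PER_DEG,
                        y_deg = pos$y_um / UM_PER_DEG)
  e <- which(neurons$cls == "E"); i <- which(neurons$cls == "I")
  ring <- function(v) cbind(pre = v, post = c(v[-1], v[1]))
  graph <- structure(list(
    ee = ring(e), ei = cbind(pre = e, post = i[(seq_along(e) - 1) %% 5 + 1]),
    ie = cbind(pre = i, post = e[seq_along(i)]), ii = ring(i),
    l6e = cbind(pre = integer(0), post = integer(0)),
    l6i = cbind(pre = integer(0), post = integer(0)),
    kernels = wiring_kernels(), n_neurons = 20L), class = "connectivity_graph")
  neurons$lgn_inputs <- replicate(20, integer(0), simplify = FALSE)
  neurons$n_lgn <- 0L
  cfg <- default_config("mini")
  structure(list(grid = grid, neurons = neurons,
                 mosaic = build_lgn_mosaic(c(-0.1, 0.35, -0.1, 0.35),
                                           seed = seed),
                 graph = graph,
                 l6_units = data.frame(id = integer(0), x_um = numeric(0),
                                       y_um = numeric(0)),
                 l6_members = list(), config = cfg, seed = as.integer(seed)),
            class = "v1_network")
}

#' Named experiment recipes
#'
#' Stimulus batteries reproducing the standard figure protocols:
#' \describe{
#'   \item{fig3_contrast}{contrast sweep at the preferred orientation and
#'     2.5 c/d, plus the orthogonal orientation, for contrast-response
#'     curves and current decomposition.}
#'   \item{fig4_knockdown}{high-contrast optimal grating with the E->E
#'     coupling scaled to 100/75/50/0\% of reference.}
#'   \item{fig5_tuning}{8 orientations x 7 contrasts (and a 10-sf sweep at
#'     the preferred orientation) for tuning-vs-contrast.}
#'   \item{fig7_maps}{five orientations at 64\% contrast for activity maps.}
#'   \item{fig8_maps_vs_contrast}{orientations x contrasts for map
#'     stability.}
#' }
#'
#' @param name recipe name.
#' @param scale "mini" shrinks the batteries for CI-speed runs.
#' @return list of class `experiment_recipe` with `name`, a data.frame
#'   `battery` (one simulation per row: `contrast`, `orientation_deg`,
#'   `sf_cpd`, `s_ee_scale`, `l6_scale`) and `duration_s`.
#' @export
experiment_recipe <- function(name = c("fig3_contrast", "fig4_knockdown",
                                       "fig5_tuning", "fig7_maps",
                                       "fig8_maps_vs_contrast"),
                              scale = c("reduced", "mini", "full")) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  mini <- scale == "mini"
  contrasts7 <- c(0.05, 0.1, 0.2, 0.33, 0.5, 0.64, 1)
  battery <- switch(name,
    fig3_contrast = {
      cs <- if (mini) c(0.1, 0.5, 1) else c(0, contrasts7)
      expand.grid(contrast = cs, orientation_deg = c(0, 90), sf_cpd = 2.5,
                  s_ee_scale = 1, l6_scale = 1)
    },
    fig4_knockdown =
      expand.grid(contrast = if (mini) 1 else c(0.1, 0.33, 0.64, 1),
                  orientation_deg = 0, sf_cpd = 2.5,
                  s_ee_scale = c(1, 0.75, 0.5, 0), l6_scale = 1)[
        if (mini) c(1, 2, 3, 4) else TRUE, ],
    fig5_tuning = {
      oris <- if (mini) c(0, 45, 90, 135) else seq(-90, 67.5, by = 22.5) %% 180
      cs <- if (mini) c(0.1, 0.64) else contrasts7
      ori_part <- expand.grid(contrast = cs, orientation_deg = oris,
                              sf_cpd = 2.5, s_ee_scale = 1, l6_scale = 1)
      sfs <- if (mini) c(1, 2.5, 5) else c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 7, 10)
      sf_part <- expand.grid(contrast = cs, orientation_deg = 0,
                             sf_cpd = sfs, s_ee_scale = 1, l6_scale = 1)
      unique(rbind(ori_part, sf_part))
    },
    fig7_maps =
      expand.grid(contrast = 0.64,
                  orientation_deg = if (mini) c(0, 90) else c(0, 30, 60, 90, 120),
                  sf_cpd = 2.5, s_ee_scale = 1, l6_scale = 1),
    fig8_maps_vs_contrast =
      expand.grid(contrast = if (mini) c(0.1, 1) else c(0.1, 0.33, 0.64, 1),
                  orientation_deg = if (mini) 0 else c(0, 60, 120),
                  sf_cpd = 2.5, s_ee_scale = 1, l6_scale = 1))
  structure(list(name = name, battery = battery,
                 duration_s = if (mini) 2 else 10),
            class = "experiment_recipe")
}

#' Run an experiment recipe
#'
#' One simulation per battery row, each with an independent seed substream
#' derived from the master seed.  Failed simulations are recorded and the
#' batch continues; results carry a manifest (config hash, seed, battery).
#'
#' @param recipe an [experiment_recipe()] (or its name).
#' @param network a built `v1_network`.
#' @param seed master seed.
#' @param duration_s override the recipe duration.
#' @param keep_sims keep the full simulation objects (memory-hungry);
#'   otherwise only per-neuron rates and mean currents are retained.
#' @param quiet suppress progress.
#' @return list of class `experiment_result`: `recipe`, `battery`,
#'   `rates` (neurons x simulations matrix), `currents` (list),
#'   `errors` (character per row, NA if ok), `manifest`.
#' @export
run_experiment <- function(recipe, network, seed = 1L, duration_s = NULL,
                           keep_sims = FALSE, quiet = TRUE) {
  if (is.character(recipe)) recipe <- experiment_recipe(recipe)
  bat <- recipe$battery
  dur <- duration_s %||% recipe$duration_s
  n <- nrow(network$neurons)
  rates <- matrix(NA_real_, n, nrow(bat))
  currents <- vector("list", nrow(bat))
  sims <- if (keep_sims) vector("list", nrow(bat)) else NULL
  errors <- rep(NA_character_, nrow(bat))
  for (k in seq_len(nrow(bat))) {
    if (!quiet) message(sprintf("simulation %d/%d", k, nrow(bat)))
    res <- tryCatch({
      spec <- grating_spec(contrast = bat$contrast[k],
                           orientation_deg = bat$orientation_deg[k],
                           sf_cpd = bat$sf_cpd[k])
      ws <- c(S_ee = bat$s_ee_scale[k], l6 = bat$l6_scale[k])
      sim <- run_simulation(network, spec, duration_s = dur,
                            seed = sub_seed(seed, "experiment") + k,
                            weight_scales = ws)
      rates[, k] <- mean_rates(sim)$rate_sps
      currents[[k]] <- sim$currents
      if (keep_sims) sims[[k]] <- sim
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors[k] <- res
  }
  if (any(!is.na(errors)))
    warning(sprintf("%d/%d simulations failed", sum(!is.na(errors)), nrow(bat)))
  structure(list(recipe = recipe, battery = bat, rates = rates,
                 currents = currents, sims = sims, errors = errors,
                 manifest = list(seed = as.integer(seed),
                                 config_hash = config_hash(network$config),
                                 duration_s = dur, n_simulations = nrow(bat))),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s: %d simulations of %.1f s (%d failed)\n",
              x$recipe$name, nrow(x$battery), x$manifest$duration_s,
              sum(!is.na(x$errors))))
  invisible(x)
}
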