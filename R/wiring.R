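#' Distance-dependent Gaussian wiring kernels
#'
#' Connection probability between two L4 cells falls off as a Gaussian of
#' their cortical distance, truncated at a per-projection cutoff radius;
#' connection *strength* is distance independent.  Presynaptic E cells have
#' kernel SD 200/sqrt(2) um and presynaptic I cells 125/sqrt(2) um.  Peak
#' probabilities are ~15\% for E->E and 60\% for E->I, I->E and I->I.
#'
#' Cutoff radii are calibrated once, in closed form, so that the expected
#' interior in-degrees hit the anatomical targets (an E-cell has ~200 E and
#' ~100 I presynaptic cells; an I-cell ~750 E and ~100 I): with a peak p,
#' kernel SD s and presynaptic density rho the untruncated expectation is
#' U = p * rho * 2*pi*s^2, and truncation at
#' r_c = s * sqrt(2 * log(U / (U - target))) leaves exactly `target`.
#'
#' @param density neurons per hypercolumn (E:I split 3:1).
#' @param peak named numeric: peak probabilities for `ee`, `ei` (E->I),
#'   `ie` (I->E), `ii`.
#' @param targets named numeric: intended mean interior in-degrees
#'   (number of presynaptic cells) for the four projections.
#' @return object of class `wiring_kernels`: per-projection `peak`,
#'   `sd_um`, `cutoff_um`.
#' @examples
#' wiring_kernels()$cutoff_um
#' @export
wiring_kernels <- function(density = 4000,
                           peak = c(ee = 0.15, ei = 0.6, ie = 0.6, ii = 0.6),
                           targets = c(ee = 200, ei = 750, ie = 100, ii = 100)) {
  rho_e <- 0.75 * density / HC_SIDE_UM^2   # E cells per um^2
  rho_i <- 0.25 * density / HC_SIDE_UM^2
  sd_e <- 200 / sqrt(2)
  sd_i <- 125 / sqrt(2)
  sds <- c(ee = sd_e, ei = sd_e, ie = sd_i, ii = sd_i)
  rhos <- c(ee = rho_e, ei = rho_e, ie = rho_i, ii = rho_i)
  cutoff <- vapply(names(sds), function(p) {
    if (peak[[p]] <= 0) return(0)        # disabled projection
    U <- peak[[p]] * rhos[[p]] * 2 * pi * sds[[p]]^2
    if (U <= targets[[p]])
      stop_config("wiring_kernels: projection %s cannot reach target in-degree %g (untruncated expectation %.1f)",
                  p, targets[[p]], U)
    sds[[p]] * sqrt(2 * log(U / (U - targets[[p]])))
  }, numeric(1))
  structure(list(peak = peak, sd_um = sds, cutoff_um = cutoff,
                 targets = targets, density = density),
            class = "wiring_kernels")
}

#' @export
print.wiring_kernels <- function(x, ...) {
  cat("<wiring_kernels>\n")
  print(data.frame(peak = x$peak, sd_um = round(x$sd_um, 1),
                   cutoff_um = round(x$cutoff_um, 1), target = x$targets))
  invisible(x)
}

#' Sample the recurrent L4 connectivity
#'
#' Draws every potential edge as an independent Bernoulli variable with
#' probability `peak * exp(-d^2 / (2 sd^2))` for cortical distance `d` up to
#' the cutoff radius (zero beyond), separately for the four projection types.
#' Self-edges are excluded.  Deterministic given the seed.
#'
#' @param neurons neuron table from [build_sheet()].
#' @param kernels a [wiring_kernels()] object.
#' @param seed integer seed.
#' @return list of class `connectivity_graph` with integer edge matrices
#'   `ee`, `ei`, `ie`, `ii` (columns `pre`, `post`; ids index `neurons`),
#'   plus the kernels used.
#' @export
sample_recurrent_connectivity <- function(neurons, kernels, seed = 1L) {
  e <- which(neurons$cls == "E")
  i <- which(neurons$cls == "I")
  pre_sets <- list(ee = e, ei = e, ie = i, ii = i)
  post_sets <- list(ee = e, ei = i, ie = e, ii = i)
  edges <- with_seed(seed, {
    lapply(names(pre_sets), function(p) {
      pre <- pre_sets[[p]]; post <- post_sets[[p]]
      if (kernels$peak[[p]] <= 0)
        return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("pre", "post"))))
      m <- sample_gaussian_edges_cpp(
        neurons$x_um[pre], neurons$y_um[pre],
        neurons$x_um[post], neurons$y_um[post],
        kernels$peak[[p]], kernels$sd_um[[p]], kernels$cutoff_um[[p]],
        identical(pre, post))
      cbind(pre = pre[m[, 1]], post = post[m[, 2]])
    })
  })
  names(edges) <- names(pre_sets)
  structure(c(edges, list(kernels = kernels, n_neurons = nrow(neurons))),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat("<connectivity_graph>\n")
  for (p in c("ee", "ei", "ie", "ii", "l6e", "l6i"))
    if (!is.null(x[[p]])) cat(sprintf("  %-4s %d edges\n", p, nrow(x[[p]])))
  invisible(x)
}

#' Summarise in/out-degrees per projection type
#'
#' Mean and SD of the in-degree (presynaptic count per postsynaptic cell)
#' and out-degree per projection, over all cells and over interior cells
#' only (at least one kernel-cutoff radius from every sheet edge, to avoid
#' open-boundary bias).
#'
#' @param graph a [sample_recurrent_connectivity()] result (optionally with
#'   `l6e`/`l6i` entries added by [wire_l6()]).
#' @param neurons the neuron table.
#' @param grid the [hc_grid()] the sheet was built on.
#' @return data.frame with one row per projection: `proj`, `n_edges`,
#'   `in_mean`, `in_sd`, `in_mean_interior`, `out_mean`.
#' @export
degree_report <- function(graph, neurons, grid) {
  projs <- intersect(c("ee", "ei", "ie", "ii", "l6e", "l6i"), names(graph))
  post_cls <- c(ee = "E", ei = "I", ie = "E", ii = "I", l6e = "E", l6i = "I")
  rows <- lapply(projs, function(p) {
    ed <- graph[[p]]
    post <- which(neurons$cls == post_cls[[p]])
    margin <- if (p %in% c("l6e", "l6i")) 360 else graph$kernels$cutoff_um[[p]]
    interior <- post[interior_mask(grid, neurons$x_um[post],
                                   neurons$y_um[post], margin)]
    indeg <- tabulate(match(ed[, "post"], post), nbins = length(post))
    names(indeg) <- post
    outdeg <- if (nrow(ed)) as.numeric(table(ed[, "pre"])) else 0
    data.frame(proj = p, n_edges = nrow(ed),
               in_mean = mean(indeg), in_sd = sd(indeg),
               in_mean_interior =
                 if (length(interior)) mean(indeg[as.character(interior)]) else NA_real_,
               out_mean = mean(outdeg))
  })
  do.call(rbind, rows)
}
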