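#' Build the full model network
#'
#' Runs the whole construction pipeline: hypercolumn grid and neuron sheet,
#' LGN mosaic and template-based afferent assignment, recurrent Gaussian
#' wiring, L6 unit placement and wiring, and the L6 rate-estimation
#' memberships (L4 neurons within 75 um of each unit).  Everything is
#' derived from the config and the master seed through named substreams, so
#' the same (config, seed) pair reproduces the network bit for bit.
#'
#' @param config a [default_config()]-style configuration.
#' @param seed master integer seed.
#' @param quiet suppress progress messages.
#' @return object of class `v1_network`: `grid`, `neurons`, `mosaic`,
#'   `graph` (edge lists `ee`, `ei`, `ie`, `ii`, `l6e`, `l6i`),
#'   `l6_units`, `l6_members` (list per unit), `config`, `seed`.
#' @export
build_network <- function(config = default_config("mini"), seed = 1L,
                          quiet = TRUE) {
  validate_config(config, allow_out_of_range = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  grid <- hc_grid(config$grid$n_rows, config$grid$n_cols)
  say("sheet: %d x %d HC", grid$n_rows, grid$n_cols)
  neurons <- build_sheet(grid, config$density$per_hc,
                         seed = sub_seed(seed, "sheet"))
  m <- config$lgn$margin_deg
  extent <- c(-m, grid$n_cols * DEG_PER_HC + m,
              -m, grid$n_rows * DEG_PER_HC + m)
  mosaic <- build_lgn_mosaic(extent, config$lgn$spacing_deg,
                             config$lgn$jitter_sd_deg,
                             seed = sub_seed(seed, "mosaic"))
  say("mosaic: %d cells; assigning afferents...", nrow(mosaic))
  neurons <- assign_lgn_inputs(neurons, mosaic,
                               seed = sub_seed(seed, "lgn_assign"),
                               n_input_probs = config$lgn$n_input_probs,
                               p_aligned = config$lgn$p_aligned,
                               i_lgn_inputs = config$lgn$i_inputs,
                               max_match_deg = config$lgn$max_match_deg)
  kernels <- wiring_kernels(config$density$per_hc, config$kernels$peak,
                            config$kernels$targets)
  say("recurrent wiring...")
  graph <- sample_recurrent_connectivity(neurons, kernels,
                                         seed = sub_seed(seed, "wiring"))
  l6_units <- place_l6_units(grid, config$l6$units_per_hc)
  say("L6 wiring (%d units)...", nrow(l6_units))
  l6 <- wire_l6(neurons, l6_units, seed = sub_seed(seed, "l6"),
                e_range = config$l6$e_indegree_range,
                i_range = config$l6$i_indegree_range,
                p_near = config$l6$p_near,
                r_near = config$l6$r_near_um, r_far = config$l6$r_far_um)
  graph$l6e <- l6$l6e
  graph$l6i <- l6$l6i
  members <- l6_memberships(neurons, l6_units, config$l6$member_radius_um)
  structure(list(grid = grid, neurons = neurons, mosaic = mosaic,
                 graph = graph, l6_units = l6_units, l6_members = members,
                 config = config, seed = as.integer(seed)),
            class = "v1_network")
}

# list, per L6 unit, of the neuron ids within `radius_um` (both classes;
# the rate R that indexes the feedback is local L4 activity)
l6_memberships <- function(neurons, l6_units, radius_um = 75) {
  r2 <- radius_um^2
  # units lie on a regular grid; bucket neurons on that grid for speed
  xs <- sort(unique(l6_units$x_um))
  ys <- sort(unique(l6_units$y_um))
  members <- vector("list", nrow(l6_units))
  ix <- findInterval(l6_units$x_um, xs)
  iy <- findInterval(l6_units$y_um, ys)
  sx <- if (length(xs) > 1) xs[2] - xs[1] else radius_um
  sy <- if (length(ys) > 1) ys[2] - ys[1] else radius_um
  kx <- ceiling(radius_um / sx) + 1
  ky <- ceiling(radius_um / sy) + 1
  # bucket neurons by nearest unit-grid cell
  nx <- findInterval(neurons$x_um, xs - sx / 2)
  ny <- findInterval(neurons$y_um, ys - sy / 2)
  key <- paste(nx, ny)
  by_cell <- split(seq_len(nrow(neurons)), key)
  for (u in seq_len(nrow(l6_units))) {
    cand <- unlist(by_cell[paste(rep((ix[u] - kx):(ix[u] + kx),
                                     each = 2 * ky + 1),
                                 (iy[u] - ky):(iy[u] + ky))],
                   use.names = FALSE)
    if (!length(cand)) { members[[u]] <- integer(0); next }
    d2 <- (neurons$x_um[cand] - l6_units$x_um[u])^2 +
          (neurons$y_um[cand] - l6_units$y_um[u])^2
    members[[u]] <- cand[d2 <= r2]
  }
  members
}

#' @export
print.v1_network <- function(x, ...) {
  cat(sprintf("<v1_network> %d x %d HC, %d neurons (%d E / %d I), %d LGN cells, %d L6 units\n",
              x$grid$n_rows, x$grid$n_cols, nrow(x$neurons),
              sum(x$neurons$cls == "E"), sum(x$neurons$cls == "I"),
              nrow(x$mosaic), nrow(x$l6_units)))
  cat(sprintf("  edges: ee=%d ei=%d ie=%d ii=%d l6e=%d l6i=%d (seed %d)\n",
              nrow(x$graph$ee), nrow(x$graph$ei), nrow(x$graph$ie),
              nrow(x$graph$ii), nrow(x$graph$l6e), nrow(x$graph$l6i),
              x$seed))
  invisible(x)
}

#' @export
summary.v1_network <- function(object, ...) {
  rep <- degree_report(object$graph, object$neurons, object$grid)
  cat("In-degree summary (interior = one cutoff from the sheet edge):\n")
  print(rep, row.names = FALSE)
  invisible(rep)
}

#' Serialize a network to a directory of delimited text files
#'
#' Writes the neuron table, per-projection edge lists, LGN mosaic table and
#' a JSON manifest (seed, config hash, package version) so a run can be
#' reproduced or inspected outside R.
#'
#' @param network a [build_network()] result.
#' @param dir output directory (created if needed).
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- network$neurons
  write.table(data.frame(id = nt$id, x_um = nt$x_um, y_um = nt$y_um,
                         class = nt$cls, hc = nt$hc,
                         domain_deg = nt$domain_deg),
              file.path(dir, "neurons.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  for (p in c("ee", "ei", "ie", "ii", "l6e", "l6i"))
    write.table(network$graph[[p]], file.path(dir, paste0("edges_", p, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(network$mosaic[, c("id", "polarity", "x_deg", "y_deg")],
              file.path(dir, "lgn_mosaic.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  manifest <- list(seed = network$seed,
                   config_hash = config_hash(network$config),
                   package_version = as.character(utils::packageVersion("v1net")),
                   n_neurons = nrow(network$neurons))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
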