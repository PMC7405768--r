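#' Enumerate admissible LGN input templates for one orientation
#'
#' A template is a small configuration of ON/OFF LGN receptive-field centres
#' that seeds a simple-cell-like receptive field with two or three parallel
#' subregion rows aligned with the intended orientation.  Admissible
#' configurations have 2-3 rows of 1-3 cells each (at most 6 cells total),
#' rows of alternating polarity, cells within a row spaced at the mosaic
#' lattice spacing, and adjacent rows separated by 3/16 to 1/4 deg
#' (matching the cortical preference for ~2.5-3 cycles/deg).
#'
#' The triangular mosaic has three-fold rotational symmetry, so only the 0
#' and 30 degree sets are constructed directly; the 60/120 sets are exact
#' rotations of the 0 set and the 90/150 sets rotations of the 30 set.
#' Orientation 0 is vertical: rows run along the unit vector
#' (-sin(theta), cos(theta)).
#'
#' @param orientation one of 0, 30, 60, 90, 120, 150 (degrees).
#' @param row_separations candidate row separations in degrees.
#' @param cell_spacing within-row cell spacing in degrees.
#' @return list of templates; each is a list with `orientation`,
#'   `row_separation`, `n_cells` and `cells`, a data.frame of offsets
#'   `dx`, `dy` (degrees, relative to the template centre) and `polarity`.
#' @examples
#' tp <- enumerate_templates(0)
#' range(vapply(tp, function(t) t$n_cells, 1))  # 2 .. 6
#' @export
enumerate_templates <- function(orientation,
                                row_separations = c(3 / 16, 1 / 4),
                                cell_spacing = 0.125) {
  ok <- c(0, 30, 60, 90, 120, 150)
  if (!length(orientation) == 1 || !orientation %in% ok)
    stop_config("enumerate_templates: unsupported orientation %s (must be one of %s); intermediate orientations are not modeled",
                toString(orientation), toString(ok))
  # the two base sets; others are rotations (lattice 3-fold symmetry)
  base <- if (orientation %in% c(0, 60, 120)) 0 else 30
  rot <- orientation - base
  tpls <- build_template_set(base, row_separations, cell_spacing)
  if (rot != 0) tpls <- lapply(tpls, rotate_template, angle = rot)
  tpls
}

build_template_set <- function(orientation, row_separations, cell_spacing) {
  th <- orientation * pi / 180
  u <- c(-sin(th), cos(th))   # along-row (stripe) direction
  p <- c(cos(th), sin(th))    # across-row direction
  out <- list()
  for (d in row_separations) {
    for (n_rows in 2:3) {
      counts <- as.matrix(expand.grid(rep(list(1:3), n_rows)))
      counts <- counts[rowSums(counts) <= 6, , drop = FALSE]
      pol_sets <- if (n_rows == 2) list(c("ON", "OFF"), c("OFF", "ON"))
                  else list(c("ON", "OFF", "ON"), c("OFF", "ON", "OFF"))
      offs <- if (n_rows == 2) c(-d / 2, d / 2) else c(-d, 0, d)
      for (ci in seq_len(nrow(counts))) for (pol in pol_sets) {
        cells <- do.call(rbind, lapply(seq_len(n_rows), function(r) {
          m <- counts[ci, r]
          along <- (seq_len(m) - (m + 1) / 2) * cell_spacing
          data.frame(dx = offs[r] * p[1] + along * u[1],
                     dy = offs[r] * p[2] + along * u[2],
                     polarity = pol[r])
        }))
        out[[length(out) + 1L]] <-
          list(orientation = orientation, row_separation = d,
               n_rows = n_rows, n_cells = nrow(cells), cells = cells)
      }
    }
  }
  out
}

#' Rotate a template by a multiple of 30 degrees
#'
#' Rotates the cell offsets counterclockwise and updates the orientation
#' label modulo 180.
#'
#' @param template a template from [enumerate_templates()].
#' @param angle rotation angle in degrees.
#' @export
rotate_template <- function(template, angle) {
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- as.matrix(template$cells[, c("dx", "dy")]) %*% t(R)
  template$cells$dx <- xy[, 1]
  template$cells$dy <- xy[, 2]
  template$orientation <- (template$orientation + angle) %% 180
  template
}

#' Match LGN mosaic cells to cortical neurons through templates
#'
#' Each excitatory neuron draws a target LGN input count from
#' `n_input_probs` (over 0..6).  Neurons with a target of >= 2 are given a
#' template: with probability `p_aligned` a template of the neuron's wedge
#' orientation, otherwise one of a random other orientation (so a majority
#' of cells in every wedge carries the wedge's intended orientation).  The
#' chosen template is centred at the neuron's retinotopic position
#' (cortex mapped at 0.25 deg/HC) and each template slot is matched to the
#' nearest unused-in-this-template mosaic cell of the required polarity;
#' among templates of the right orientation and size the one with the
#' smallest total squared matching distance wins, ties broken by lowest
#' template index.  Neurons with a target of 0-1 (complex-cell seeds) get
#' that many nearest cells regardless of polarity.  Inhibitory neurons get
#' `i_lgn_inputs` nearest cells regardless of polarity (their feedforward
#' drive is untuned; selectivity of I-cells is inherited from the network).
#'
#' @param neurons neuron table from [build_sheet()].
#' @param mosaic LGN mosaic from [build_lgn_mosaic()].
#' @param templates named list of template sets indexed by orientation
#'   (as produced internally when `NULL`).
#' @param seed integer seed.
#' @param n_input_probs probabilities of an E-cell having 0..6 LGN inputs;
#'   default skewed toward 4-6 so simple cells are in the majority.
#' @param p_aligned probability that a template matches the wedge
#'   orientation (default 0.85).
#' @param i_lgn_inputs LGN inputs per I-cell (default 3).
#' @param max_match_deg maximum slot-to-cell matching distance.
#' @return `neurons` with a list-column `lgn_inputs` (integer vectors of
#'   mosaic ids), an integer column `n_lgn`, and `lgn_orientation` (the
#'   orientation of the assigned template, NA for untemplated cells).
#' @export
assign_lgn_inputs <- function(neurons, mosaic, templates = NULL, seed = 1L,
                              n_input_probs = c(0.08, 0.06, 0.06, 0.10,
                                                0.20, 0.25, 0.25),
                              p_aligned = 0.85, i_lgn_inputs = 3L,
                              max_match_deg = 0.1) {
  stopifnot(length(n_input_probs) == 7)
  oris <- c(0, 30, 60, 90, 120, 150)
  if (is.null(templates))
    templates <- setNames(lapply(oris, enumerate_templates), oris)
  ex <- mosaic$x_deg; ey <- mosaic$y_deg
  is_on <- mosaic$polarity == "ON"
  res <- with_seed(seed, {
    n <- nrow(neurons)
    n_lgn <- integer(n)
    ori_used <- rep(NA_real_, n)
    inputs <- vector("list", n)
    e_idx <- which(neurons$cls == "E")
    tgt <- sample(0:6, length(e_idx), replace = TRUE, prob = n_input_probs)
    aligned <- runif(length(e_idx)) < p_aligned
    loc_r2 <- (0.5 + max_match_deg)^2  # template radius + matching slack
    for (k in seq_along(e_idx)) {
      i <- e_idx[k]
      cx <- neurons$x_deg[i]; cy <- neurons$y_deg[i]
      if (tgt[k] <= 1) {
        if (tgt[k] == 1) {
          j <- nearest_cells(ex, ey, cx, cy, 1L)
          inputs[[i]] <- mosaic$id[j]; n_lgn[i] <- 1L
        }
        next
      }
      loc <- which((ex - cx)^2 + (ey - cy)^2 < loc_r2)
      ori <- if (aligned[k]) neurons$domain_deg[i] else
        sample(setdiff(oris, neurons$domain_deg[i]), 1L)
      cand <- Filter(function(t) t$n_cells == tgt[k], templates[[as.character(ori)]])
      if (!length(cand))
        cand <- templates[[as.character(ori)]]
      best <- NULL; best_cost <- Inf
      for (t in cand) {
        m <- match_template(t, cx, cy, ex[loc], ey[loc], is_on[loc], max_match_deg)
        if (!is.null(m) && m$cost < best_cost) { best <- m; best_cost <- m$cost }
      }
      if (is.null(best))
        stop_config("assign_lgn_inputs: no mosaic cells within matching distance of neuron %d at (%.3f, %.3f) deg",
                    neurons$id[i], cx, cy)
      best$cells <- loc[best$cells]
      inputs[[i]] <- mosaic$id[best$cells]
      n_lgn[i] <- length(best$cells)
      ori_used[i] <- ori
    }
    for (i in which(neurons$cls == "I")) {
      j <- nearest_cells(ex, ey, neurons$x_deg[i], neurons$y_deg[i],
                         as.integer(i_lgn_inputs))
      inputs[[i]] <- mosaic$id[j]; n_lgn[i] <- length(j)
    }
    list(inputs = inputs, n_lgn = n_lgn, ori = ori_used)
  })
  neurons$lgn_inputs <- res$inputs
  neurons$n_lgn <- res$n_lgn
  neurons$lgn_orientation <- res$ori
  neurons
}

nearest_cells <- function(ex, ey, cx, cy, k) {
  d2 <- (ex - cx)^2 + (ey - cy)^2
  order(d2)[seq_len(min(k, length(d2)))]
}

# Greedy slot-to-cell matching of one template instance centred at (cx, cy).
# Returns NULL if any slot has no unused cell of the right polarity within
# `max_d` degrees.
match_template <- function(t, cx, cy, ex, ey, is_on, max_d) {
  used <- integer(0)
  cost <- 0
  cells <- integer(t$n_cells)
  for (s in seq_len(t$n_cells)) {
    sx <- cx + t$cells$dx[s]; sy <- cy + t$cells$dy[s]
    pool <- if (t$cells$polarity[s] == "ON") which(is_on) else which(!is_on)
    pool <- setdiff(pool, used)
    d2 <- (ex[pool] - sx)^2 + (ey[pool] - sy)^2
    j <- which.min(d2)
    if (!length(j) || d2[j] > max_d^2) return(NULL)
    cells[s] <- pool[j]
    used <- c(used, pool[j])
    cost <- cost + d2[j]
  }
  list(cells = cells, cost = cost)
}
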