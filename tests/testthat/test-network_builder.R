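test_that("sheet has the printed density, 3:1 E:I split and full domain labels", {
  nt <- build_sheet(hc_grid(1, 1), seed = 3)
  expect_equal(nrow(nt), 4000)
  expect_equal(sum(nt$cls == "E"), 3000)
  expect_equal(sum(nt$cls == "I"), 1000)

  nt9 <- build_sheet(hc_grid(3, 3), seed = 3)
  expect_equal(nrow(nt9), 36000)
  expect_equal(sum(nt9$cls == "E"), 3 * sum(nt9$cls == "I"))
  expect_true(all(nt9$hc %in% 1:9))
  expect_true(all(nt9$domain_deg %in% seq(0, 150, 30)))
  # every wedge of every HC is populated
  expect_equal(nrow(unique(nt9[, c("hc", "wedge")])), 54)
  # arbitrary density keeps the exact 3:1 ratio
  nt_odd <- build_sheet(hc_grid(1, 2), density = 1234, seed = 3)
  expect_equal(sum(nt_odd$cls == "E"), 3 * sum(nt_odd$cls == "I"))
})

test_that("sheet construction is deterministic and validates inputs", {
  a <- build_sheet(hc_grid(1, 1), seed = 5)
  b <- build_sheet(hc_grid(1, 1), seed = 5)
  expect_identical(a, b)
  expect_error(build_sheet(hc_grid(1, 1), density = -1), "density")
  expect_error(hc_grid(0, 1), "n_rows")
})

test_that("wedges are counterclockwise with 30-degree orientation steps", {
  g <- hc_grid(1, 1)
  # points at increasing polar angle around the pinwheel centre
  ang <- seq(10, 350, by = 60) * pi / 180
  x <- 250 + 100 * cos(ang)
  y <- 250 + 100 * sin(ang)
  w <- wedge_index(g, x, y, rep(1L, 6))
  expect_equal(w, 1:6)
  expect_equal(g$wedge_angles[w], seq(0, 150, 30))
})

test_that("LGN mosaic has equal ON/OFF density and ~10 cells per HC region", {
  m <- build_lgn_mosaic(c(-0.3, 1.05, -0.3, 1.05), jitter_sd = 0.02, seed = 2)
  counts <- lgn_cells_per_hc(m, 3, 3)
  expect_equal(nrow(counts), 9)
  expect_gte(mean(counts$n), 9)
  expect_lte(mean(counts$n), 11)
  # ON and OFF close to 50/50 overall
  expect_lt(abs(sum(counts$n_on) - sum(counts$n_off)) / sum(counts$n), 0.15)
})

test_that("unjittered OFF cells sit at barycentres (equidistant from ON vertices)", {
  m <- build_lgn_mosaic(c(0, 1, 0, 1), jitter_sd = 0, seed = 1)
  on <- m[m$polarity == "ON", ]
  off <- m[m$polarity == "OFF", ]
  # check a handful of interior OFF cells: distances to the 3 nearest ON
  # cells are equal (barycentre of an equilateral triangle)
  inner <- which(off$x_deg > 0.2 & off$x_deg < 0.8 &
                 off$y_deg > 0.2 & off$y_deg < 0.8)[1:10]
  for (k in inner) {
    d <- sort(sqrt((on$x_deg - off$x_deg[k])^2 + (on$y_deg - off$y_deg[k])^2))
    expect_equal(d[1], d[2], tolerance = 1e-9)
    expect_equal(d[2], d[3], tolerance = 1e-9)
  }
})

test_that("empirical ON density matches the triangular-lattice closed form", {
  s <- 0.125
  m <- build_lgn_mosaic(c(-2, 2, -2, 2), spacing = s, jitter_sd = 0.02,
                        seed = 4)
  # count in the central 3x3 deg to avoid edge effects
  on <- m$polarity == "ON" & abs(m$x_deg) < 1.5 & abs(m$y_deg) < 1.5
  dens <- sum(on) / 9
  expect_equal(dens, 2 / (sqrt(3) * s^2), tolerance = 0.02)
})

test_that("mosaic validates its extent", {
  expect_error(build_lgn_mosaic(c(0, 0.1, 0, 0.1)), "smaller than one HC")
  expect_error(build_lgn_mosaic(c(0, 1, 0, 1), spacing = 0), "spacing")
})

test_that("templates obey the row/cell-count and separation constraints", {
  for (ori in c(0, 30)) {
    tp <- enumerate_templates(ori)
    expect_gt(length(tp), 10)
    for (t in tp) {
      expect_true(t$n_rows %in% 2:3)
      expect_lte(t$n_cells, 6)
      expect_gte(t$n_cells, 2)
      expect_true(t$row_separation >= 3 / 16 - 1e-9 &&
                    t$row_separation <= 1 / 4 + 1e-9)
      # row polarities alternate
      expect_true(all(table(t$cells$polarity) <= 6))
    }
  }
  expect_error(enumerate_templates(45), "unsupported orientation")
})

test_that("rotating the 60-degree set back by -60 recovers the 0-degree set", {
  t0 <- enumerate_templates(0)
  t60 <- enumerate_templates(60)
  expect_equal(length(t0), length(t60))
  back <- lapply(t60, rotate_template, angle = -60)
  for (k in seq_along(t0)) {
    expect_equal(back[[k]]$cells$dx, t0[[k]]$cells$dx, tolerance = 1e-12)
    expect_equal(back[[k]]$cells$dy, t0[[k]]$cells$dy, tolerance = 1e-12)
    expect_equal(as.character(back[[k]]$cells$polarity),
                 as.character(t0[[k]]$cells$polarity))
  }
  # 90/150 are rotations of the 30 set
  t150 <- enumerate_templates(150)
  t30 <- lapply(t150, rotate_template, angle = -120)
  expect_equal(t30[[1]]$cells$dx, enumerate_templates(30)[[1]]$cells$dx,
               tolerance = 1e-12)
})

test_that("LGN input assignment favours the wedge orientation and is seeded", {
  net <- get_mini_net()
  nt <- net$neurons
  e <- nt$cls == "E" & !is.na(nt$lgn_orientation)
  # per-wedge majority carries the wedge's intended orientation
  for (d in seq(0, 150, 30)) {
    sel <- e & nt$domain_deg == d
    expect_gt(mean(nt$lgn_orientation[sel] == d), 0.5)
  }
  expect_true(all(nt$n_lgn[nt$cls == "E"] <= 6))
  # complex-cell seeds (0-1 LGN inputs) exist
  expect_gt(sum(nt$n_lgn[nt$cls == "E"] <= 1), 0)
  # determinism
  net2 <- make_fixture("mini", seed = 42L)
  expect_identical(net$neurons$lgn_inputs, net2$neurons$lgn_inputs)
})

test_that("recurrent wiring hits the printed interior in-degrees", {
  # full-density 2x2 sheet: interior exists for the I-kernel cutoffs and
  # the E-kernel statistics are checked on the central region
  kern <- wiring_kernels()
  nt <- build_sheet(hc_grid(2, 2), seed = 9)
  g <- sample_recurrent_connectivity(nt, kern, seed = 9)
  grid <- hc_grid(2, 2)
  rep <- degree_report(g, nt, grid)
  rep <- setNames(split(rep, rep$proj), sort(unique(rep$proj)))
  # I-presynaptic kernels (cutoff ~172 um) have a true interior here
  expect_equal(rep$ie$in_mean_interior, 100, tolerance = 0.15)
  expect_equal(rep$ii$in_mean_interior, 100, tolerance = 0.15)
  # E-presynaptic kernels: compare cells near the sheet centre
  ctr <- function(cls) which(nt$cls == cls &
    abs(nt$x_um - 500) < 150 & abs(nt$y_um - 500) < 150)
  indeg <- tabulate(g$ee[, "post"], nbins = nrow(nt))
  expect_equal(mean(indeg[ctr("E")]), 200, tolerance = 0.15)
  indeg_ei <- tabulate(g$ei[, "post"], nbins = nrow(nt))
  expect_equal(mean(indeg_ei[ctr("I")]), 750, tolerance = 0.15)
})

test_that("zero peak probability gives an empty projection", {
  kern <- wiring_kernels(peak = c(ee = 0, ei = 0.6, ie = 0.6, ii = 0.6))
  nt <- build_sheet(hc_grid(1, 1), density = 400, seed = 2)
  g <- sample_recurrent_connectivity(nt, kern, seed = 2)
  expect_equal(nrow(g$ee), 0)
  expect_gt(nrow(g$ei), 0)
})

test_that("wiring is deterministic and has no self-edges", {
  kern <- wiring_kernels()
  nt <- build_sheet(hc_grid(1, 1), density = 800, seed = 6)
  g1 <- sample_recurrent_connectivity(nt, kern, seed = 13)
  g2 <- sample_recurrent_connectivity(nt, kern, seed = 13)
  expect_identical(g1$ee, g2$ee)
  expect_identical(g1$ie, g2$ie)
  expect_false(any(g1$ee[, "pre"] == g1$ee[, "post"]))
  expect_false(any(g1$ii[, "pre"] == g1$ii[, "post"]))
})

test_that("degree_report matches brute-force counting on a toy graph", {
  net <- get_unit_net()
  rep <- degree_report(net$graph, net$neurons, net$grid)
  # brute force: every projection has one edge per pre cell (ring / match)
  ee <- net$graph$ee
  post_e <- which(net$neurons$cls == "E")
  brute_in <- vapply(post_e, function(j) sum(ee[, "post"] == j), 1)
  expect_equal(rep$in_mean[rep$proj == "ee"], mean(brute_in))
  expect_equal(rep$n_edges[rep$proj == "ee"], nrow(ee))
  # invariant to edge-list ordering
  net2 <- net
  net2$graph$ee <- net$graph$ee[rev(seq_len(nrow(net$graph$ee))), ]
  rep2 <- degree_report(net2$graph, net2$neurons, net2$grid)
  expect_equal(rep2$in_mean, rep$in_mean)
})

test_that("L6 wiring respects the in-degree ranges and contact radii", {
  net <- get_mini_net()
  nt <- net$neurons
  indeg_e <- tabulate(net$graph$l6e[, "post"], nbins = nrow(nt))
  indeg_i <- tabulate(net$graph$l6i[, "post"], nbins = nrow(nt))
  e <- nt$cls == "E"; i <- nt$cls == "I"
  expect_true(all(indeg_e[e] >= 38 & indeg_e[e] <= 55))
  expect_true(all(indeg_i[i] >= 100 & indeg_i[i] <= 110))
  expect_gte(mean(indeg_i[i]), 100)
  expect_lte(mean(indeg_i[i]), 110)
  # anticorrelation with LGN count: 0-LGN cells at the top of the range
  zero_lgn <- e & nt$n_lgn == 0
  expect_gt(mean(indeg_e[zero_lgn]), 52)
  expect_lt(cor(nt$n_lgn[e], indeg_e[e]), -0.8)
  # ~5/6 of contacts within 180 um of the postsynaptic cell
  ed <- net$graph$l6e
  d <- sqrt((net$l6_units$x_um[ed[, "pre"]] - nt$x_um[ed[, "post"]])^2 +
            (net$l6_units$y_um[ed[, "pre"]] - nt$y_um[ed[, "post"]])^2)
  expect_equal(mean(d <= 180), 5 / 6, tolerance = 0.05)
  expect_true(all(d <= 360 + 1e-9))
})

test_that("L6 units are evenly placed at 300 per hypercolumn", {
  g <- hc_grid(1, 3)
  u <- place_l6_units(g)
  expect_equal(nrow(u), 900)
  hc <- hc_index(g, u$x_um, u$y_um)
  expect_equal(as.numeric(table(hc)), rep(300, 3))
})

test_that("network serialization round-trips through text files", {
  net <- get_unit_net()
  dir <- withr::local_tempdir()
  write_network(net, dir)
  nt <- read.table(file.path(dir, "neurons.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(nt), 20)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 42L)
  ee <- read.table(file.path(dir, "edges_ee.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(ee), nrow(net$graph$ee))
})
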