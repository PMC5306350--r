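spec8 <- lattice_spec(8)

test_that("unwrapping reconstructs chains across periodic boundaries", {
  ch <- rod_chain(3)
  expect_equal(unwrap_chain(ch, spec8), to_cartesian(ch))
  straddle <- chain_mat(c(7, 0), c(0, 0), c(1, 0))
  xy <- unwrap_chain(straddle, spec8)
  expect_equal(unname(diff(xy[, "x"])), c(1, 1))  # collinear, span 2
  expect_equal(unname(xy[3, "x"] - xy[1, "x"]), 2)
  # telescoping: bond vectors sum to the end-to-end vector
  set.seed(31)
  p <- sample_saw_pivot(12, 10)
  ch2 <- chain_mat(cbind(p[, 1] %% 32, p[, 2] %% 32))
  xy2 <- unwrap_chain(ch2, lattice_spec(32))
  bonds <- diff(xy2)
  expect_equal(colSums(bonds), xy2[nrow(xy2), ] - xy2[1, ])
  expect_equal(unname(sqrt(rowSums(bonds^2))), rep(1, 11))
  expect_error(unwrap_chain(chain_mat(c(0, 0), c(2, 0)), spec8), "broken")
})

test_that("radius of gyration matches hand-computed references", {
  expect_equal(radius_of_gyration_sq(rod_chain(2), spec8), 0.25)
  expect_equal(radius_of_gyration_sq(rod_chain(3), spec8), 2 / 3)
  disk <- make_disk()
  expect_equal(radius_of_gyration_sq(disk$state$beads, disk$state$spec), 6 / 7)
})

test_that("gyration tensor eigenvalues and the trace identity", {
  ev <- gyration_eigenvalues(rod_chain(3), spec8)
  expect_equal(ev, c(0, 2 / 3), tolerance = 1e-12)
  disk <- make_disk()
  evd <- gyration_eigenvalues(disk$state$beads, disk$state$spec)
  expect_equal(evd, c(3 / 7, 3 / 7), tolerance = 1e-12)
  # trace identity on arbitrary chains
  set.seed(5)
  for (i in 1:5) {
    p <- sample_saw_pivot(15, 8)
    ch <- chain_mat(cbind(p[, 1] %% 32, p[, 2] %% 32))
    sp <- lattice_spec(32)
    expect_equal(sum(gyration_eigenvalues(ch, sp)),
                 radius_of_gyration_sq(ch, sp), tolerance = 1e-12)
  }
})

test_that("asphericity is a ratio of means with the rod and disk anchors", {
  rods <- t(vapply(3:12, function(n) gyration_eigenvalues(rod_chain(n), lattice_spec(16)),
                   numeric(2)))
  expect_equal(asphericity(rods), 1, tolerance = 1e-12)
  disk <- make_disk()
  evd <- gyration_eigenvalues(disk$state$beads, disk$state$spec)
  expect_equal(asphericity(evd[1], evd[2]), 0, tolerance = 1e-12)
  # equal-size rod + disk mix: ratio of means gives exactly 1/2
  s <- 2
  expect_equal(asphericity(c(0, s / 2), c(s, s / 2)), 0.5)
  expect_error(asphericity(c(0, 0), c(0, 0)), "degenerate")
})

test_that("end-to-end distance on reference chains", {
  expect_equal(end_to_end_sq(rod_chain(3), spec8), 4)
  expect_equal(end_to_end_sq(rod_chain(2), spec8), 1)
  hairpin <- chain_mat(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(end_to_end_sq(hairpin, spec8), 1)
})

test_that("intramolecular correlation has exact weights and normalisation", {
  g2 <- intramolecular_correlation(rod_chain(2), spec8)
  expect_equal(g2$weight[g2$r == 0], 1)
  expect_equal(g2$weight[g2$r == 1], 1)
  g3 <- intramolecular_correlation(rod_chain(3), spec8)
  expect_equal(g3$weight[g3$r == 1], 4 / 3)
  expect_equal(g3$weight[g3$r == 2], 2 / 3)
  # total ordered-pair weight is N for any chain
  set.seed(9)
  p <- sample_saw_pivot(14, 8)
  ch <- chain_mat(cbind(p[, 1] %% 32, p[, 2] %% 32))
  g <- intramolecular_correlation(ch, lattice_spec(32))
  expect_equal(sum(g$weight), 14)
})

test_that("structure factor limits, closed forms, and the hexagon oracle", {
  g2 <- intramolecular_correlation(rod_chain(2), spec8)
  q <- exp(seq(log(0.05), log(3), length.out = 40))
  s <- structure_factor(g2, q = q)
  expect_equal(s$S, 1 + sin(q) / q, tolerance = 1e-12)
  expect_equal(structure_factor(g2, q = 1e-6)$S, 2, tolerance = 1e-3)

  disk <- make_disk()
  gd <- intramolecular_correlation(disk$state)
  sd_ <- structure_factor(gd, q = q)
  # independent oracle: direct double sum over the 7 beads
  xy <- unwrap_chain(disk$state$beads, disk$state$spec)
  direct <- vapply(q, function(qi) {
    d <- as.matrix(dist(xy))
    k <- ifelse(d == 0, 1, sin(qi * d) / (qi * d))
    sum(k) / 7
  }, numeric(1))
  expect_equal(sd_$S, direct, tolerance = 1e-10)
  expect_error(structure_factor(gd, q = c(-1, 1)), "positive")
  # Bessel kernel variant is finite and equals N at q -> 0
  sb <- structure_factor(gd, q = 1e-6, kernel = "bessel")
  expect_equal(sb$S, 7, tolerance = 1e-3)
})

test_that("observables are invariant under periodic translation of the system", {
  set.seed(12)
  p <- sample_saw_pivot(16, 8)
  sp <- lattice_spec(32)
  ch <- chain_mat(cbind(p[, 1] %% 32, p[, 2] %% 32))
  shifted <- chain_mat(cbind((p[, 1] + 13) %% 32, (p[, 2] + 27) %% 32))
  expect_equal(radius_of_gyration_sq(ch, sp),
               radius_of_gyration_sq(shifted, sp), tolerance = 1e-12)
  expect_equal(gyration_eigenvalues(ch, sp),
               gyration_eigenvalues(shifted, sp), tolerance = 1e-12)
  g1 <- intramolecular_correlation(ch, sp)
  g2 <- intramolecular_correlation(shifted, sp)
  expect_equal(g1$r, g2$r)
  expect_equal(g1$weight, g2$weight)
})

test_that("center-of-mass pair correlation normalises to 1 for uniform points", {
  pts <- lapply(1:40, function(i) make_uniform_points(60, 32, seed = i)$points)
  bins <- seq(2, 16, 2)
  g <- point_pair_correlation(pts, lattice_spec(32), bins = bins)
  # continuum annulus normalisation: per-bin values wobble by the lattice
  # shell granularity, but the plateau averages to 1
  expect_true(all(abs(g$table$g - 1) < 0.2))
  expect_equal(mean(g$table$g), 1, tolerance = 0.05)
  # exact oracle: expected pair counts from the lattice distance shells
  spec <- lattice_spec(32)
  others <- as.matrix(expand.grid(a = 0:31, b = 0:31))[-1, ]
  shell_d <- vapply(seq_len(nrow(others)), function(i)
    minimum_image_distance(c(0, 0), others[i, ], spec), numeric(1))
  frac <- tabulate(findInterval(shell_d, bins, rightmost.closed = TRUE),
                   nbins = length(bins))[seq_len(length(bins) - 1)] / 1023
  expected <- choose(60, 2) * frac * 40
  expect_true(all(abs(g$table$pairs - expected) < 4 * sqrt(expected)))
  # two chains at a known separation: all weight in that bin
  st <- build_initial(run_config(4, 2, 16), arrangement = "spread")
  g2 <- cm_pair_correlation(st, bins = seq(0, 8, 1))
  cm <- cma2d:::cm_axial(st)
  d <- cma2d:::axial_pair_dists(cm, 16)
  hit <- findInterval(d, seq(0, 8, 1), rightmost.closed = TRUE)
  expect_equal(which(g2$table$pairs > 0), hit)
  expect_error(cm_pair_correlation(build_initial(run_config(4, 1, 16))), "2 chains")
})

test_that("a melt shows a correlation hole in the cm pair correlation", {
  states <- list()
  st <- build_initial(run_config(16, 64, 32), arrangement = "random", seed = 8)
  for (i in 1:10) {
    r <- cma_run(st, 200, seed = 40 + i, measure_every = 0)
    st <- r$state
    states[[i]] <- st
  }
  g <- cm_pair_correlation(states, bins = seq(0, 16, 1))
  expect_lt(mean(g$table$g[1:2]), 0.7)          # strong exclusion at r << Rg
  expect_equal(mean(tail(g$table$g, 4)), 1, tolerance = 0.15)
})

test_that("solvent domain sizes match an independent graph-component oracle", {
  st <- build_initial(run_config(2, 1, 8))
  expect_equal(sum(solvent_cluster_sizes(st)), 62)

  st2 <- build_initial(run_config(8, 10, 16), arrangement = "pivot", seed = 6)
  r <- cma_run(st2, 300, seed = 7, measure_every = 0)
  sizes <- sort(solvent_cluster_sizes(r$state))
  expect_equal(sum(sizes), 16^2 - 80)
  skip_if_not_installed("igraph")
  occ <- cma2d:::occupancy(r$state)
  nbr <- cma2d:::neighbor_table(r$state$spec)
  solvent <- which(occ == 0L)
  edges <- do.call(rbind, lapply(solvent, function(s) {
    nb <- nbr[s, ]
    nb <- nb[occ[nb] == 0L & nb > s]
    if (length(nb)) cbind(s, nb) else NULL
  }))
  gr <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE,
                                      vertices = data.frame(name = solvent))
  oracle <- sort(as.integer(igraph::components(gr)$csize))
  expect_equal(sizes, oracle)

  melt <- build_initial(run_config(16, 16, 16))
  expect_length(solvent_cluster_sizes(melt), 0)
})
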