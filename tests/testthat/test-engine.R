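test_that("proposals build closed loops with zero net displacement", {
  spec <- lattice_spec(6)
  set.seed(11)
  loops <- list()
  while (length(loops) < 50) {
    l <- propose_loop(spec)
    if (!is.null(l)) loops[[length(loops) + 1L]] <- l
  }
  lens <- vapply(loops, function(l) nrow(l$sites), integer(1))
  expect_true(all(lens >= 3))
  expect_true(any(lens == 3))  # triangles are the minimal loops
  for (l in loops) {
    expect_equal(colSums(l$steps), c(da = 0, db = 0, dlayer = 0))
    expect_equal(anyDuplicated(apply(l$sites, 1, paste, collapse = ",")), 0L)
  }
})

test_that("a loop and its reverse are proposed equally often", {
  # tally the two orientations of one specific triangle on a small box
  spec <- lattice_spec(4)
  key <- function(l) paste(apply(l$sites, 1, paste, collapse = ","),
                           collapse = "|")
  fwd <- "0,0,0|1,0,0|0,1,0"   # s0 -> +a -> (0,1) -> closes
  rev <- "0,0,0|0,1,0|1,0,0"
  set.seed(13)
  n_fwd <- 0L; n_rev <- 0L
  for (i in 1:100000) {
    l <- propose_loop(spec)
    if (is.null(l) || nrow(l$sites) != 3L) next
    k <- key(l)
    if (k == fwd) n_fwd <- n_fwd + 1L
    if (k == rev) n_rev <- n_rev + 1L
  }
  expect_gt(n_fwd + n_rev, 25)
  p <- 0.5
  z <- (n_fwd - (n_fwd + n_rev) * p) / sqrt((n_fwd + n_rev) * p * (1 - p))
  expect_lt(abs(z), 3)
})

test_that("direction choices are uniform", {
  set.seed(17)
  tally <- tabulate(replicate(3e4, sample.int(6L, 1L)), 6L)
  expect_gt(stats::chisq.test(tally)$p.value, 1e-3)
})

test_that("apply_loop accepts solvent rotations and rejects bond stretchers", {
  st <- build_initial(run_config(4, 1, 8))  # rod at row b = 0
  solvent_tri <- structure(list(
    sites = chain_mat(c(0, 4), c(1, 4), c(0, 5)),
    steps = NULL), class = "cooperative_loop")
  res <- apply_loop(st, solvent_tri)
  expect_true(res$accepted)
  expect_identical(res$state$beads, st$beads)  # only solvent moved

  # triangle through one interior bead: would stretch its bonds
  bead_tri <- structure(list(
    sites = chain_mat(c(1, 0), c(1, 1), c(0, 1)),
    steps = NULL), class = "cooperative_loop")
  res2 <- apply_loop(st, bead_tri)
  expect_false(res2$accepted)
  expect_identical(res2$state, st)
})

test_that("applying a loop then its reverse is the identity", {
  st <- build_initial(run_config(6, 3, 8))
  set.seed(23)
  n_checked <- 0L
  while (n_checked < 20L) {
    l <- propose_loop(st$spec)
    if (is.null(l)) next
    res <- apply_loop(st, l)
    if (!res$accepted) next
    back <- apply_loop(res$state, reverse_loop(l))
    expect_true(back$accepted)
    expect_identical(back$state$beads, st$beads)
    st <- res$state  # walk the chain forward to vary configurations
    n_checked <- n_checked + 1L
  }
})

test_that("engine trajectories are deterministic in the seed and conserve state invariants", {
  st <- build_initial(run_config(8, 4, 16))
  r1 <- cma_run(st, 1500, seed = 5, measure_every = 50)
  r2 <- cma_run(st, 1500, seed = 5, measure_every = 50)
  expect_identical(r1$state$beads, r2$state$beads)
  expect_identical(r1$measurements, r2$measurements)
  r3 <- cma_run(st, 1500, seed = 6, measure_every = 50)
  expect_false(identical(r1$state$beads, r3$state$beads))
  expect_length(validate_state(r1$state), 0)

  r0 <- cma_run(st, 0, seed = 5, measure_every = 10)
  expect_identical(r0$state$beads, st$beads)
  expect_equal(nrow(r0$measurements), 0L)

  # time accounting: one time unit per site-count of attempted displacements
  expect_gte(r1$stats$displacements, 1500 * st$spec$n_sites)
  expect_lt(r1$stats$displacements, 1500 * st$spec$n_sites + 100)
  expect_lte(r1$stats$accepted, r1$stats$attempts)
})

test_that("engine-side chain metrics agree with the R observable suite", {
  st <- build_initial(run_config(12, 6, 16), arrangement = "random", seed = 2)
  r <- cma_run(st, 500, seed = 3, measure_every = 0)
  st <- r$state
  m <- cma2d:::chain_metrics_cpp(st$beads, st$spec$edge, st$spec$layers,
                                 st$N, st$n_chains)
  for (i in seq_len(st$n_chains)) {
    ch <- cma2d:::get_chain(st, i)
    expect_equal(unname(m[i, "rg2"]), radius_of_gyration_sq(ch, st$spec),
                 tolerance = 1e-10)
    expect_equal(unname(m[i, "ree2"]), end_to_end_sq(ch, st$spec),
                 tolerance = 1e-10)
    ev <- gyration_eigenvalues(ch, st$spec)
    expect_equal(unname(m[i, c("lambda1", "lambda2")]), ev, tolerance = 1e-10)
  }
})

test_that("equilibrate converges quickly on an already-equilibrated ensemble", {
  st <- build_initial(run_config(8, 8, 24), arrangement = "pivot", seed = 4)
  eq <- equilibrate(st, seed = 9, window = 400, max_windows = 40)
  expect_true(eq$converged)
  expect_lte(nrow(eq$history), 15)
  expect_length(validate_state(eq$state), 0)
})

test_that("relaxation from the extended start decreases Rg^2 towards a plateau", {
  st <- build_initial(run_config(16, 1, 32))
  start_rg2 <- radius_of_gyration_sq(cma2d:::get_chain(st, 1), st$spec)
  expect_equal(start_rg2, (16^2 - 1) / 12)
  r <- cma_run(st, 12000, seed = 21, measure_every = 100)
  m <- r$measurements$rg2_mean
  first <- mean(head(m, 30)); last <- mean(tail(m, 30))
  expect_lt(last, first)
  expect_lt(last, start_rg2 / 2)
})
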