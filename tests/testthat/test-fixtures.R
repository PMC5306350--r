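test_that("every fixture reference value is reproduced by the observables", {
  fixtures <- c(lapply(c(3L, 5L, 8L, 32L), make_rod), list(make_disk()))
  for (f in fixtures) {
    st <- f$state
    ev <- gyration_eigenvalues(st$beads, st$spec)
    got <- list(rg2 = radius_of_gyration_sq(st$beads, st$spec),
                ree2 = end_to_end_sq(st$beads, st$spec),
                lambda1 = ev[1], lambda2 = ev[2],
                A2 = asphericity(ev[1], ev[2]))
    for (ref in f$reference)
      expect_equal(got[[ref$observable]], ref$value, tolerance = ref$tol,
                   label = paste(f$name, ref$observable))
    expect_length(validate_state(st), 0)
  }
  expect_error(make_rod(10, L = 8), "capacity")
})

test_that("rod closed form matches the direct sum at every length", {
  for (n in c(2L, 7L, 20L, 50L)) {
    f <- make_rod(n)
    expect_equal(radius_of_gyration_sq(f$state$beads, f$state$spec),
                 (n^2 - 1) / 12, tolerance = 1e-12)
  }
})

test_that("SAW enumeration reproduces published walk counts and exact moments", {
  expect_equal(enumerate_saws(2)$count, 6)
  expect_equal(enumerate_saws(3)$count, 30)
  expect_equal(enumerate_saws(4)$count, 138)
  expect_equal(enumerate_saws(5)$count, 618)
  e3 <- enumerate_saws(3)
  expect_equal(mean(e3$ree2), 12 / 5)  # (2*3 + 2*1 + 4)/5 by angle classes
  expect_equal(enumerate_saws(2)$ree2, rep(1, 6), tolerance = 1e-12)
  expect_error(enumerate_saws(11), "guard")
  expect_error(enumerate_saws(1), "guard")
})

test_that("ideal walk generator has exact mean end-to-end and is reproducible", {
  w <- sample_ideal_walks(32, 10000, seed = 7)
  se <- sd(w$ree2) / sqrt(length(w$ree2))
  expect_lt(abs(mean(w$ree2) - 31) / se, 3)
  w2 <- sample_ideal_walks(32, 10000, seed = 7)
  expect_identical(w$ree2, w2$ree2)
  w3 <- sample_ideal_walks(32, 100, seed = 8)
  expect_false(identical(w3$ree2[1:100], w$ree2[1:100]))
})

test_that("pivot sampler draws valid SAWs with the exact N=8 mean Rg^2", {
  set.seed(19)
  e <- enumerate_saws(8)
  samples <- replicate(250, {
    p <- sample_saw_pivot(8, 12)
    expect_equal(anyDuplicated(p[, 1] + 1i * p[, 2]), 0L)
    steps <- diff(p)
    expect_true(all(steps[, 1]^2 + steps[, 1] * steps[, 2] + steps[, 2]^2 == 1))
    rg2_points(p)
  })
  se <- sd(samples) / sqrt(length(samples))
  expect_lt(abs(mean(samples) - mean(e$rg2)) / se, 3.5)
})

test_that("uniform point fixture behaves as an ideal gas", {
  u <- make_uniform_points(50, 16, seed = 3)
  expect_equal(anyDuplicated(u$points[, 1] + 1i * u$points[, 2]), 0L)
  u2 <- make_uniform_points(50, 16, seed = 3)
  expect_identical(u$points, u2$points)
})

test_that("fixture export writes snapshots plus a reference JSON", {
  dir <- tempfile()
  paths <- write_fixtures(dir, rod_N = c(3L, 8L))
  expect_true(all(file.exists(file.path(dir, c("rod_N3.snap", "rod_N8.snap",
                                               "disk_hexagon.snap",
                                               "reference.json")))))
  back <- read_snapshot(file.path(dir, "rod_N8.snap"))
  expect_equal(back$N, 8L)
  expect_length(validate_state(back), 0)
  refs <- jsonlite::read_json(file.path(dir, "reference.json"))
  expect_equal(refs$rod_N3[[1]]$value, (3^2 - 1) / 12, tolerance = 1e-12)
})
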