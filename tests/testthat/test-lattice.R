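test_that("neighbour topology matches the triangular lattice with periodic wrap", {
  spec <- lattice_spec(8)
  nb <- neighbors(c(0, 0), spec)
  expect_equal(nrow(nb), 6L)
  got <- apply(nb[, 1:2], 1L, paste, collapse = ",")
  want <- c("1,0", "7,0", "0,1", "0,7", "1,7", "7,1")
  expect_setequal(got, want)

  spec2 <- lattice_spec(8, 2)
  nb2 <- neighbors(c(3, 3, 0), spec2)
  expect_equal(nrow(nb2), 7L)
  expect_true(any(nb2[, 1] == 3 & nb2[, 2] == 3 & nb2[, 3] == 1))
})

test_that("neighbour relation is symmetric and regular", {
  set.seed(42)
  for (spec in list(lattice_spec(5), lattice_spec(8, 2))) {
    for (i in 1:20) {
      s <- c(sample.int(spec$edge, 1) - 1L, sample.int(spec$edge, 1) - 1L,
             sample.int(spec$layers, 1) - 1L)
      nb <- neighbors(s, spec)
      expect_equal(nrow(nb), spec$coordination)
      expect_equal(anyDuplicated(apply(nb, 1, paste, collapse = ",")), 0L)
      for (j in seq_len(nrow(nb))) {
        back <- neighbors(nb[j, ], spec)
        expect_true(any(back[, 1] == s[1] & back[, 2] == s[2] &
                          back[, 3] == s[3]))
      }
    }
  }
  expect_error(neighbors(c(9, 0), lattice_spec(8)), "range")
})

test_that("cartesian embedding has unit bonds", {
  expect_equal(unname(to_cartesian(c(0, 0))[1, ]), c(0, 0))
  expect_equal(unname(to_cartesian(c(0, 1))[1, ]), c(0.5, sqrt(3) / 2))
  expect_equal(unname(to_cartesian(c(2, 2))[1, ]), c(3, sqrt(3)))
  uv <- cma2d:::unit_vectors()
  lens <- sqrt((uv[, 1] + uv[, 2] / 2)^2 + 3 / 4 * uv[, 2]^2)
  expect_equal(lens, rep(1, 6))
})

test_that("minimum image agrees with brute force over periodic images", {
  spec <- lattice_spec(8)
  expect_equal(minimum_image_distance(c(0, 0), c(7, 0), spec), 1)
  expect_equal(minimum_image_distance(c(3, 3), c(3, 3), spec), 0)
  expect_equal(minimum_image_distance(c(0, 0), c(4, 0), spec), 4)

  brute <- function(s1, s2, L) {
    best <- Inf
    for (m in -1:1) for (n in -1:1) {
      da <- s2[1] - s1[1] + m * L; db <- s2[2] - s1[2] + n * L
      best <- min(best, sqrt((da + db / 2)^2 + 3 / 4 * db^2))
    }
    best
  }
  set.seed(7)
  pts <- matrix(sample.int(8, 60, replace = TRUE) - 1L, ncol = 2L)
  for (i in seq(1, 29, 2)) {
    s1 <- pts[i, ]; s2 <- pts[i + 1, ]
    expect_equal(minimum_image_distance(s1, s2, spec), brute(s1, s2, 8))
    # integer-r2 kernel agrees with the R implementation
    expect_equal(cma2d:::min_image_r2_cpp(s1[1], s1[2], 0L, s2[1], s2[2], 0L, 8L),
                 round(brute(s1, s2, 8)^2))
  }
  # triangle inequality on sampled triples
  for (i in 1:10) {
    tri <- matrix(sample.int(8, 6, replace = TRUE) - 1L, ncol = 2L)
    d12 <- minimum_image_distance(tri[1, ], tri[2, ], spec)
    d23 <- minimum_image_distance(tri[2, ], tri[3, ], spec)
    d13 <- minimum_image_distance(tri[1, ], tri[3, ], spec)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("off-lattice concentration conversion uses the close-packing constant", {
  expect_equal(close_packing_fraction(), pi / (2 * sqrt(3)))
  expect_equal(phi_area(1), pi / (2 * sqrt(3)))
  expect_equal(phi_area(0.5), 0.5 * pi / (2 * sqrt(3)))
})
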