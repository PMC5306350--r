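# Deterministic reference configurations and stochastic reference ensembles
# with exactly known observables.  These are the oracles against which the
# observable suite and the sampling engine are tested.

new_fixture <- function(name, state, reference) {
  structure(list(name = name, state = state, reference = reference),
            class = "fixture")
}

#' @export
print.fixture <- function(x, ...) {
  cat(sprintf("Fixture '%s':\n", x$name))
  for (r in x$reference)
    cat(sprintf("  %s = %g  (%s)\n", r$observable, r$value, r$provenance))
  invisible(x)
}

#' Rod fixture: a fully extended chain
#'
#' A collinear N-bead chain along the `a` axis.  Closed-form references:
#' `Rg^2 = (N^2 - 1)/12`, `Ree^2 = (N - 1)^2`, smaller eigenvalue
#' `lambda1 = 0`, and asphericity 1 for any ensemble of rods.
#'
#' @param N Beads (>= 2); must fit in the box edge.
#' @param L Box edge (default: smallest power-of-two-free fit `>= N + 1`).
#' @return A `fixture` whose `$state` is a `polymer_system`.
#' @export
make_rod <- function(N, L = max(4L, N + 1L)) {
  N <- as.integer(N)
  if (N < 2L) stop("a rod needs N >= 2", call. = FALSE)
  if (N > L) stop("capacity error: rod longer than the box edge", call. = FALSE)
  spec <- lattice_spec(L)
  beads <- cbind(a = 0:(N - 1L), b = 0L, layer = 0L)
  state <- structure(list(spec = spec, N = N, n_chains = 1L,
                          phi = concentration(1L, N, spec), timestep = 0,
                          beads = beads),
                     class = "polymer_system")
  new_fixture(sprintf("rod_N%d", N), state, list(
    list(observable = "rg2", value = (N^2 - 1) / 12, tol = 1e-12,
         provenance = "closed form: variance of N unit-spaced collinear points"),
    list(observable = "ree2", value = (N - 1)^2, tol = 1e-12,
         provenance = "closed form"),
    list(observable = "lambda1", value = 0, tol = 1e-12,
         provenance = "collinear => rank-1 tensor"),
    list(observable = "A2", value = 1, tol = 1e-12,
         provenance = "fully extended chain")))
}

#' Disk fixture: hexagon plus center
#'
#' A 7-bead chain visiting the six vertices of a unit hexagon and its
#' center (a valid bonded path).  Six-fold symmetry forces an isotropic
#' gyration tensor: `lambda1 = lambda2 = 3/7`, `Rg^2 = 6/7`, asphericity 0.
#'
#' @param L Box edge (>= 5).
#' @return A `fixture`.
#' @export
make_disk <- function(L = 8L) {
  spec <- lattice_spec(L)
  # ring walked vertex to vertex, center last; offset keeps coords in range
  ring <- rbind(c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, 0L),
                c(-1L, 1L), c(0L, 1L), c(0L, 0L))
  beads <- cbind(a = (ring[, 1L] + 2L) %% L, b = (ring[, 2L] + 2L) %% L,
                 layer = 0L)
  colnames(beads) <- c("a", "b", "layer")
  state <- structure(list(spec = spec, N = 7L, n_chains = 1L,
                          phi = concentration(1L, 7L, spec), timestep = 0,
                          beads = beads),
                     class = "polymer_system")
  new_fixture("disk_hexagon", state, list(
    list(observable = "rg2", value = 6 / 7, tol = 1e-12,
         provenance = "6 beads at unit distance from the center bead"),
    list(observable = "lambda1", value = 3 / 7, tol = 1e-12,
         provenance = "six-fold symmetry => isotropic tensor"),
    list(observable = "lambda2", value = 3 / 7, tol = 1e-12,
         provenance = "six-fold symmetry"),
    list(observable = "A2", value = 0, tol = 1e-12,
         provenance = "disk")))
}

#' Exhaustive self-avoiding walk enumeration
#'
#' Enumerates every directed self-avoiding walk of `N` beads on the
#' unbounded triangular lattice (starting at the origin; translations
#' removed by fixing the start), with the exact `Rg^2` and `Ree^2` of each
#' walk.  This is the brute-force oracle for the dilute single-chain limit
#' of the CMA engine: in an athermal system every conformation is equally
#' probable.
#'
#' @param N Beads, `2 <= N <= 10` (the count grows roughly five-fold per
#'   bead).
#' @return List with `count`, `steps` (walks x (N-1) matrix of direction
#'   indices into the 6 unit vectors), and per-walk `rg2`, `ree2`.
#' @export
enumerate_saws <- function(N) {
  N <- as.integer(N)
  if (N < 2L || N > 10L)
    stop("enumeration guard: N must be between 2 and 10", call. = FALSE)
  saw_enumerate_cpp(N)
}

#' Ideal (unrestricted) random walks on the triangular lattice
#'
#' Samples `M` walks of `N` beads whose steps are i.i.d. uniform over the
#' six unit vectors, without excluded volume.  Exact references:
#' `<Ree^2> = N - 1` (uncorrelated unit steps), and the chain-length
#' scaling exponent of `Rg^2` is `2nu = 1`.
#'
#' @param N Beads per walk.
#' @param M Number of walks.
#' @param seed RNG seed (uses R's RNG, restored on exit).
#' @return List with matrices `x`, `y` (M x N Cartesian coordinates) and
#'   per-walk vectors `rg2`, `ree2`.
#' @export
sample_ideal_walks <- function(N, M, seed = 1L) {
  stopifnot(N >= 2L, M >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  uv <- unit_vectors()
  dirs <- matrix(sample.int(6L, M * (N - 1L), replace = TRUE), M, N - 1L)
  dx <- matrix(uv[dirs, 1L] + uv[dirs, 2L] / 2, M, N - 1L)
  dy <- matrix(uv[dirs, 2L] * sqrt(3) / 2, M, N - 1L)
  x <- cbind(0, t(apply(dx, 1L, cumsum)))
  y <- cbind(0, t(apply(dy, 1L, cumsum)))
  rg2 <- rowMeans((x - rowMeans(x))^2 + (y - rowMeans(y))^2)
  ree2 <- (x[, N] - x[, 1L])^2 + (y[, N] - y[, 1L])^2
  list(x = x, y = y, rg2 = rg2, ree2 = ree2)
}

#' Sample a self-avoiding walk by the pivot algorithm
#'
#' Draws a self-avoiding walk of `N` beads on the unbounded triangular
#' lattice, asymptotically uniform over all SAWs: starting from the
#' extended walk, random point-group symmetries of the lattice (12
#' elements: 6 rotations, 6 reflections) are applied to the tail segment
#' at a random pivot bead and accepted when the result is self-avoiding.
#' The pivot algorithm decorrelates global observables in a handful of
#' accepted pivots, so `n_sweeps * N` attempts give an effectively
#' equilibrated conformation.
#'
#' @param N Beads (>= 2).
#' @param n_sweeps Attempted pivots per bead (default 20).
#' @return Integer matrix of axial coordinates (columns `a`, `b`),
#'   translated so all coordinates are non-negative.
#' @export
sample_saw_pivot <- function(N, n_sweeps = 20L) {
  stopifnot(N >= 2L)
  # the 12 point-group elements as 2x2 integer matrices on axial coords
  rot <- matrix(c(0L, 1L, -1L, 1L), 2L)       # 60 degree rotation
  mir <- matrix(c(1L, 0L, 1L, -1L), 2L)       # reflection
  syms <- list(diag(2L))
  for (k in 1:5) syms[[k + 1L]] <- syms[[k]] %*% rot
  syms <- c(syms, lapply(syms, function(s) s %*% mir))
  pts <- cbind(a = 0:(N - 1L), b = 0L)
  for (i in seq_len(n_sweeps * N)) {
    k <- sample.int(N - 1L, 1L)               # pivot bead index (1..N-1)
    s <- syms[[sample.int(12L, 1L)]]
    head <- pts[seq_len(k), , drop = FALSE]
    tail_ <- pts[(k + 1L):N, , drop = FALSE]
    piv <- pts[k, ]
    moved <- sweep(tail_, 2L, piv) %*% t(s)
    moved <- sweep(moved, 2L, piv, `+`)
    cand <- rbind(head, moved)
    if (!anyDuplicated(cand[, 1L] + 1i * cand[, 2L])) pts <- cand
  }
  pts <- sweep(pts, 2L, apply(pts, 2L, min))
  colnames(pts) <- c("a", "b")
  storage.mode(pts) <- "integer"
  pts
}

#' Uniform random site pattern
#'
#' `n` distinct sites drawn uniformly from a single-layer box — the
#' ideal-gas reference for the pair-correlation normalisation
#' (`g(r) = 1` at every resolvable distance).
#'
#' @param n Number of points (>= 2).
#' @param L Box edge.
#' @param seed RNG seed (uses R's RNG, restored on exit).
#' @return List with `points` (n x 2 axial coordinates) and `spec`.
#' @export
make_uniform_points <- function(n, L, seed = 1L) {
  stopifnot(n >= 2L, n <= L^2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(L^2, n) - 1L
  list(points = cbind(a = s %% L, b = s %/% L), spec = lattice_spec(L))
}

#' Write all deterministic fixtures to a directory
#'
#' Serialises the rod and disk fixtures in the snapshot text format next to
#' a JSON file of their reference values, so they exercise the snapshot
#' reader/writer.
#'
#' @param dir Output directory (created if missing).
#' @param rod_N Rod lengths to write.
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(dir, rod_N = c(3L, 8L, 32L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fixtures <- c(lapply(rod_N, make_rod), list(make_disk()))
  paths <- character(0)
  refs <- list()
  for (f in fixtures) {
    p <- file.path(dir, paste0(f$name, ".snap"))
    write_snapshot(f$state, p)
    paths <- c(paths, p)
    refs[[f$name]] <- lapply(f$reference, function(r)
      list(observable = r$observable, value = r$value, tol = r$tol,
           provenance = r$provenance))
  }
  jp <- file.path(dir, "reference.json")
  jsonlite::write_json(refs, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
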