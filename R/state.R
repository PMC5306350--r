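#' Simulation run configuration
#'
#' Bundles and validates the parameters of one CMA run: chain length `N`,
#' number of chains, box edge `L`, layer count, RNG seed, run length in
#' time units (one time unit = one attempted displacement per lattice site
#' on average), measurement interval and the maximum cooperative-loop
#' length.
#'
#' @param N Beads per chain (>= 2).
#' @param n_chains Number of chains (>= 1); `n_chains * N` must not exceed
#'   the site count.
#' @param L Box edge (sites per side, >= 4).
#' @param layers 1 or 2.
#' @param seed Integer RNG seed.
#' @param n_timesteps Production run length in time units.
#' @param measure_every Timesteps between measurements (0 = no measurement).
#' @param max_loop Maximum number of sites in a cooperative loop.
#' @param eq_window,eq_tol_se,eq_max_windows Equilibration criterion: window
#'   width in timesteps, the tolerance in combined standard errors, and the
#'   cap on the number of windows (see [equilibrate()]).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(N, n_chains, L, layers = 1L, seed = 1L,
                       n_timesteps = 1000L, measure_every = 10L,
                       max_loop = 100L, eq_window = 500L, eq_tol_se = 2,
                       eq_max_windows = 200L) {
  spec <- lattice_spec(L, layers)
  N <- as.integer(N); n_chains <- as.integer(n_chains)
  if (N < 2L) stop("N must be >= 2", call. = FALSE)
  if (n_chains < 1L) stop("n_chains must be >= 1", call. = FALSE)
  if (n_chains * N > spec$n_sites)
    stop(sprintf("capacity error: %d beads do not fit in %d sites",
                 n_chains * N, spec$n_sites), call. = FALSE)
  if (max_loop < 3L) stop("max_loop must be >= 3", call. = FALSE)
  if (n_timesteps < 0L) stop("n_timesteps must be >= 0", call. = FALSE)
  structure(list(N = N, n_chains = n_chains, L = spec$edge,
                 layers = spec$layers, spec = spec, seed = as.integer(seed),
                 n_timesteps = as.numeric(n_timesteps),
                 measure_every = as.integer(measure_every),
                 max_loop = as.integer(max_loop),
                 eq_window = as.integer(eq_window),
                 eq_tol_se = as.numeric(eq_tol_se),
                 eq_max_windows = as.integer(eq_max_windows)),
            class = "run_config")
}

#' Polymer concentration
#'
#' The fraction of lattice sites occupied by polymer beads,
#' `phi = n_chains * N / (layers * L^2)`.  All remaining sites hold solvent
#' particles; `phi = 1` is a melt.
#'
#' @param n_chains Number of chains.
#' @param N Beads per chain.
#' @param spec A [lattice_spec()].
#' @return The concentration as a numeric scalar.
#' @examples
#' concentration(1, 1024, lattice_spec(256))  # 0.015625
#' @export
concentration <- function(n_chains, N, spec) {
  beads <- as.numeric(n_chains) * as.numeric(N)
  if (beads > spec$n_sites)
    stop("capacity error: more beads than lattice sites", call. = FALSE)
  beads / spec$n_sites
}

# snake (boustrophedon) ordering of all sites: along a row of constant b the
# a index runs forward then backward on alternating rows; at a row end the
# path steps +1 in b; in a two-layer box it steps to layer 1 after filling
# layer 0 and retraces the snake.  Consecutive snake sites are always
# lattice neighbours, so any prefix split into chains gives unit bonds.
# A fold width w < L restricts each serpentine to a block of w columns
# (blocks filled left to right), so chains fold every w beads even when
# they would fit in a full row.
snake_sites <- function(spec, fold_width = spec$edge) {
  L <- spec$edge
  w <- as.integer(fold_width)
  stopifnot(w >= 2L, L %% w == 0L)
  block <- function(a0) {
    b <- rep(0:(L - 1L), each = w)
    a <- a0 + ifelse(b %% 2L == 0L, rep(0:(w - 1L), times = L),
                     rep((w - 1L):0, times = L))
    cbind(a = a, b = b, layer = 0L)
  }
  one <- do.call(rbind, lapply(w * (0:(L %/% w - 1L)), block))
  if (spec$layers == 2L) {
    two <- one[nrow(one):1L, , drop = FALSE]
    two[, "layer"] <- 1L
    one <- rbind(one, two)
  }
  storage.mode(one) <- "integer"
  one
}

#' Build the initial fully occupied system
#'
#' Chains are laid fully extended along the `a` axis, folding back with a
#' hairpin step (+1 in `b`) whenever a row ends, packed row by row starting
#' from the origin; every remaining site is a solvent particle.  The
#' construction is deterministic, so a configuration is fully reproducible
#' from its `run_config`.
#'
#' By default chains fold only when they hit the box edge.  A `fold_width`
#' `w < L` (a divisor of `L`, with `w * L` a multiple of `N`) lays every
#' chain as a serpentine of width `w` instead, giving each chain hairpin
#' turns from the start.  Dense systems need this: a commensurate melt of
#' fully extended chains admits no short cooperative loop that preserves
#' every bond (it is an orientationally ordered, effectively frozen
#' packing), whereas hairpin bends are the seeds through which cooperative
#' rearrangements nucleate.
#'
#' The `"random"` arrangement instead cuts a backbite-randomised
#' Hamiltonian path on the torus into consecutive N-bead chains: an exactly
#' valid full packing whose conformations are disordered from the start.
#' Dense systems (high `phi`, and the melt in particular) should be
#' initialised this way: an orientationally ordered packing of extended
#' chains admits no short cooperative loop that preserves every bond — it
#' is a jammed crystal from which loop moves cannot nucleate disorder at
#' any practical rate — whereas a disordered packing is mobile.
#'
#' @param config A [run_config()], or `N` when the remaining arguments are
#'   given directly.
#' @param n_chains,L,layers Used only when `config` is the chain length.
#' The `"spread"` arrangement lays each chain fully extended in its own
#' row, with the rows spaced evenly around the box — the natural start for
#' dilute ensembles of several chains, which would otherwise be stacked
#' into a locally dense slab.
#'
#' The `"pivot"` arrangement draws each chain's conformation from the
#' pivot-algorithm SAW sampler ([sample_saw_pivot()]) and places the
#' chains uniformly at random without overlap: for dilute systems this is
#' an equilibrium-distribution start, so production sampling is stationary
#' from the first timestep (the engine preserves the athermal uniform
#' ensemble by detailed balance).
#'
#' @param arrangement `"extended"` (the deterministic default above),
#'   `"random"` (backbite-randomised packing; single-layer boxes only),
#'   `"spread"` (one extended chain per row, rows evenly spaced; requires
#'   `N <= L` and `n_chains <= L`) or `"pivot"` (pivot-sampled SAW
#'   conformations, uniform random non-overlapping placement; single-layer,
#'   uses R's RNG).
#' @param fold_width Serpentine width in sites for the extended arrangement
#'   (default: the box edge, i.e. chains fold only at the boundary).
#' @param seed Seed for the `"random"` arrangement.
#' @return An object of class `polymer_system`: list with `spec`, `N`,
#'   `n_chains`, `phi`, `timestep` and the integer bead matrix `beads`
#'   (columns `a`, `b`, `layer`; rows ordered chain by chain, bead by bead).
#' @export
build_initial <- function(config, n_chains = NULL, L = NULL, layers = 1L,
                          arrangement = c("extended", "random", "spread",
                                          "pivot"),
                          fold_width = NULL, seed = 1) {
  if (!inherits(config, "run_config"))
    config <- run_config(N = config, n_chains = n_chains, L = L,
                         layers = layers)
  arrangement <- match.arg(arrangement)
  if (arrangement == "pivot") {
    L <- config$spec$edge
    if (config$spec$layers != 1L)
      stop("pivot arrangement supports single-layer boxes", call. = FALSE)
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    occ <- logical(L^2)
    sites <- matrix(0L, 0L, 3L)
    for (ch in seq_len(config$n_chains)) {
      placed <- FALSE
      for (try in 1:200) {
        p <- sample_saw_pivot(config$N, 20L)
        off <- c(sample.int(L, 1L), sample.int(L, 1L)) - 1L
        s <- cbind((p[, 1L] + off[1L]) %% L, (p[, 2L] + off[2L]) %% L)
        idx <- s[, 1L] + L * s[, 2L] + 1L
        if (anyDuplicated(idx) || any(occ[idx])) next
        occ[idx] <- TRUE
        sites <- rbind(sites, cbind(s, 0L))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("pivot arrangement: could not place chain ", ch,
             " without overlap", call. = FALSE)
    }
    colnames(sites) <- c("a", "b", "layer")
    storage.mode(sites) <- "integer"
  } else if (arrangement == "spread") {
    L <- config$spec$edge
    if (config$N > L || config$n_chains > L)
      stop("spread arrangement needs N <= L and n_chains <= L", call. = FALSE)
    rows <- as.integer(floor((seq_len(config$n_chains) - 1L) * L / config$n_chains))
    sites <- do.call(rbind, lapply(rows, function(r)
      cbind(a = 0:(config$N - 1L), b = r, layer = 0L)))
    storage.mode(sites) <- "integer"
  } else if (arrangement == "random") {
    if (config$spec$layers != 1L)
      stop("random arrangement supports single-layer boxes", call. = FALSE)
    L <- config$spec$edge
    sites <- backbite_path_cpp(L, 40 * L^2, as.numeric(seed))
    colnames(sites) <- c("a", "b", "layer")
  } else {
    if (is.null(fold_width)) fold_width <- config$spec$edge
    if (fold_width < config$spec$edge &&
        (fold_width * config$spec$edge) %% config$N != 0L)
      stop("fold_width * L must be a multiple of N so no chain straddles a serpentine block",
           call. = FALSE)
    sites <- snake_sites(config$spec, fold_width)
  }
  beads <- sites[seq_len(config$n_chains * config$N), , drop = FALSE]
  state <- structure(list(spec = config$spec, N = config$N,
                          n_chains = config$n_chains,
                          phi = concentration(config$n_chains, config$N,
                                              config$spec),
                          timestep = 0, beads = beads),
                     class = "polymer_system")
  state
}

#' @export
print.polymer_system <- function(x, ...) {
  cat(sprintf(
    "Polymer-solvent system: %d chain(s) of N = %d on L = %d x %d layer(s)\n",
    x$n_chains, x$N, x$spec$edge, x$spec$layers))
  cat(sprintf("  phi = %.6g, timestep = %g, solvent sites = %d\n",
              x$phi, x$timestep, x$spec$n_sites - x$n_chains * x$N))
  invisible(x)
}

# 1-based linear site index of bead rows
site_index <- function(beads, spec) {
  1L + beads[, 1L] + spec$edge * beads[, 2L] + spec$edge^2 * beads[, 3L]
}

# occupancy vector: 0 = solvent, else chain id (1-based)
occupancy <- function(state) {
  occ <- integer(state$spec$n_sites)
  occ[site_index(state$beads, state$spec)] <-
    rep(seq_len(state$n_chains), each = state$N)
  occ
}

# bead matrix of one chain (N x 3)
get_chain <- function(state, i) {
  stopifnot(i >= 1L, i <= state$n_chains)
  state$beads[((i - 1L) * state$N + 1L):(i * state$N), , drop = FALSE]
}

#' Check system invariants
#'
#' Diagnoses a `polymer_system` against the model's invariants: coordinates
#' in range, every site occupied by at most one element (full occupancy of
#' the remainder by solvent is implicit), every bond a nearest-neighbour
#' pair, and a consistent concentration.
#'
#' @param state A `polymer_system`.
#' @return Character vector of violation messages; `character(0)` when the
#'   state is valid.
#' @export
validate_state <- function(state) {
  out <- character(0)
  spec <- state$spec
  b <- state$beads
  if (nrow(b) != state$n_chains * state$N)
    out <- c(out, "bead count does not match n_chains * N")
  if (any(b[, 1L] < 0L | b[, 1L] >= spec$edge |
          b[, 2L] < 0L | b[, 2L] >= spec$edge |
          b[, 3L] < 0L | b[, 3L] >= spec$layers))
    out <- c(out, "bead coordinates out of range")
  idx <- site_index(b, spec)
  if (anyDuplicated(idx)) {
    dup <- idx[duplicated(idx)]
    out <- c(out, sprintf("double occupancy at %d site(s)", length(unique(dup))))
  }
  for (i in seq_len(state$n_chains)) {
    ch <- get_chain(state, i)
    for (j in seq_len(state$N - 1L)) {
      v <- minimum_image(ch[j, ], ch[j + 1L, ], spec)
      if (abs(sum(v^2) - 1) > 1e-9) {
        out <- c(out, sprintf("broken bond: chain %d, beads %d-%d", i, j, j + 1L))
        break
      }
    }
  }
  phi <- concentration(state$n_chains, state$N, spec)
  if (abs(phi - state$phi) > 1e-12)
    out <- c(out, "stored phi inconsistent with chain content")
  out
}

#' Write / read a snapshot in the plain-text exchange format
#'
#' The snapshot format is line-oriented and bit-exact under round-trip:
#' six header lines `L`, `layers`, `N`, `n_chains`, `phi`, `timestep`
#' (`key value`), then one line per bead `chain_id bead_index a b layer`
#' (all 0-based except `chain_id`, which is 1-based).  Solvent is implicit:
#' every unlisted site holds a solvent particle.
#'
#' @param state A `polymer_system`.
#' @param path File path.
#' @return `write_snapshot` returns `path` invisibly; `read_snapshot`
#'   returns the reconstructed `polymer_system`.
#' @export
write_snapshot <- function(state, path) {
  hdr <- c(sprintf("L %d", state$spec$edge),
           sprintf("layers %d", state$spec$layers),
           sprintf("N %d", state$N),
           sprintf("n_chains %d", state$n_chains),
           sprintf("phi %.17g", state$phi),
           sprintf("timestep %.17g", state$timestep))
  b <- state$beads
  rows <- sprintf("%d %d %d %d %d",
                  rep(seq_len(state$n_chains), each = state$N),
                  rep(seq_len(state$N) - 1L, times = state$n_chains),
                  b[, 1L], b[, 2L], b[, 3L])
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], " ", fixed = TRUE)
  keys <- vapply(hdr, `[`, "", 1L)
  vals <- vapply(hdr, `[`, "", 2L)
  if (!identical(keys, c("L", "layers", "N", "n_chains", "phi", "timestep")))
    stop("malformed snapshot header", call. = FALSE)
  h <- as.numeric(vals)
  names(h) <- keys
  body <- matrix(as.integer(unlist(strsplit(lines[-(1:6)], " ", fixed = TRUE))),
                 ncol = 5L, byrow = TRUE)
  ord <- order(body[, 1L], body[, 2L])
  body <- body[ord, , drop = FALSE]
  beads <- body[, 3:5, drop = FALSE]
  colnames(beads) <- c("a", "b", "layer")
  structure(list(spec = lattice_spec(h[["L"]], h[["layers"]]),
                 N = as.integer(h[["N"]]),
                 n_chains = as.integer(h[["n_chains"]]),
                 phi = h[["phi"]], timestep = h[["timestep"]],
                 beads = beads),
            class = "polymer_system")
}
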