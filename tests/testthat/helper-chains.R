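# shared helpers for building small reference chains in tests

# bead matrix from axial coordinate pairs
chain_mat <- function(...) {
  m <- do.call(rbind, list(...))
  if (ncol(m) == 2L) m <- cbind(m, 0L)
  colnames(m) <- c("a", "b", "layer")
  storage.mode(m) <- "integer"
  m
}

# rod of N beads along the a axis
rod_chain <- function(N, b = 0L) chain_mat(cbind(0:(N - 1L), b))

# Rg^2 of absolute axial coordinates (no periodic box involved)
rg2_points <- function(p) {
  x <- p[, 1L] + p[, 2L] / 2
  y <- p[, 2L] * sqrt(3) / 2
  mean((x - mean(x))^2 + (y - mean(y))^2)
}

# polymer_system wrapper around an explicit bead matrix
make_state <- function(beads, L, layers = 1L) {
  spec <- lattice_spec(L, layers)
  n <- nrow(beads)
  structure(list(spec = spec, N = n, n_chains = 1L,
                 phi = n / spec$n_sites, timestep = 0, beads = beads),
            class = "polymer_system")
}

# run a chunked single-chain trajectory, returning the bond-vector key of
# each sampled conformation (canonical label of its translation class)
sample_conformation_keys <- function(state, n_samples, stride, seed) {
  keys <- character(n_samples)
  for (i in seq_len(n_samples)) {
    run <- cma_run(state, stride, seed = seed + i, measure_every = 0L)
    state <- run$state
    ch <- state$beads
    da <- cma2d:::reduce_axial(diff(ch[, 1L]), state$spec$edge)
    db <- cma2d:::reduce_axial(diff(ch[, 2L]), state$spec$edge)
    keys[i] <- paste(da, db, sep = ",", collapse = ";")
  }
  keys
}
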