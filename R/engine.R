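#' Propose a cooperative loop
#'
#' Builds a closed displacement walk: starting from a uniformly chosen site,
#' each step tentatively displaces the element at the current site onto a
#' uniformly chosen neighbour, and the displaced element continues the walk.
#' The walk closes when it steps back onto the start site.  Walks that
#' revisit any other site (self-intersection), exceed `max_len` sites, or
#' close with fewer than 3 sites are rejected; rejection is a normal
#' outcome and leaves the system untouched.  The vector sum of the steps of
#' a closed loop is zero by construction (continuity condition).
#'
#' Uses R's RNG stream (`set.seed()` makes proposals reproducible).  The
#' production engine ([cma_run()]) runs the same scheme in compiled code.
#'
#' @param spec A [lattice_spec()] (or a `polymer_system`, whose spec is used;
#'   the proposal itself is independent of the occupancy).
#' @param max_len Maximum number of sites in the loop.
#' @return A `cooperative_loop` (list with `sites`, a k x 3 integer matrix,
#'   and `steps`, the k displacement vectors), or `NULL` on rejection.
#' @export
propose_loop <- function(spec, max_len = 100L) {
  if (inherits(spec, "polymer_system")) spec <- spec$spec
  L <- spec$edge
  uv <- unit_vectors()
  s0 <- c(sample.int(L, 1L) - 1L, sample.int(L, 1L) - 1L,
          sample.int(spec$layers, 1L) - 1L)
  sites <- matrix(s0, nrow = 1L)
  cur <- s0
  seen <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(s) paste(s, collapse = ",")
  assign(key(s0), TRUE, envir = seen)
  repeat {
    d <- sample.int(spec$coordination, 1L)
    if (d <= 6L) {
      nxt <- c((cur[1L] + uv[d, 1L]) %% L, (cur[2L] + uv[d, 2L]) %% L, cur[3L])
    } else {
      nxt <- c(cur[1L], cur[2L], 1L - cur[3L])
    }
    if (all(nxt == s0)) {
      if (nrow(sites) < 3L) return(NULL)
      steps <- rbind(sites[-1L, , drop = FALSE], sites[1L, , drop = FALSE]) - sites
      # report steps as true displacement vectors, not wrapped coordinates
      steps[, 1L] <- reduce_axial(steps[, 1L], L)
      steps[, 2L] <- reduce_axial(steps[, 2L], L)
      # torus-winding walks break the continuity condition: reject
      if (any(colSums(steps) != 0)) return(NULL)
      colnames(sites) <- c("a", "b", "layer")
      colnames(steps) <- c("da", "db", "dlayer")
      return(structure(list(sites = sites, steps = steps),
                       class = "cooperative_loop"))
    }
    if (!is.null(seen[[key(nxt)]])) return(NULL)
    if (nrow(sites) >= max_len) return(NULL)
    assign(key(nxt), TRUE, envir = seen)
    sites <- rbind(sites, nxt)
    cur <- nxt
  }
}

#' Reverse a cooperative loop
#'
#' The reversed loop visits the same sites in the opposite cyclic order;
#' applying a loop and then its reverse restores the original state.
#'
#' @param loop A `cooperative_loop`.
#' @return The reversed `cooperative_loop`.
#' @export
reverse_loop <- function(loop) {
  stopifnot(inherits(loop, "cooperative_loop"))
  k <- nrow(loop$sites)
  ord <- c(1L, k:2L)
  sites <- loop$sites[ord, , drop = FALSE]
  steps <- -loop$steps[c(k, (k - 1L):1L), , drop = FALSE]
  structure(list(sites = sites, steps = steps), class = "cooperative_loop")
}

#' Apply a cooperative loop if it preserves chain connectivity
#'
#' Tentatively permutes the elements cyclically along the loop (the element
#' at `sites[i]` moves to `sites[i+1]`), then accepts the move iff every
#' bond of every affected chain is still a nearest-neighbour pair.  On
#' rejection the returned state is identical to the input.  Occupancy and
#' chain identities are preserved either way: elements are only permuted,
#' never created or destroyed.
#'
#' @param state A `polymer_system`.
#' @param loop A `cooperative_loop` from [propose_loop()].
#' @return List with `state` (the possibly updated system) and `accepted`.
#' @export
apply_loop <- function(state, loop) {
  if (!inherits(loop, "cooperative_loop") || nrow(loop$sites) < 3L)
    stop("malformed loop", call. = FALSE)
  spec <- state$spec
  k <- nrow(loop$sites)
  loop_idx <- site_index(loop$sites, spec)
  if (anyDuplicated(loop_idx) > 0L) stop("malformed loop: repeated sites",
                                         call. = FALSE)
  bead_idx <- site_index(state$beads, spec)
  # occupant bead-row of each loop site (NA = solvent)
  occ <- match(loop_idx, bead_idx)
  new_beads <- state$beads
  moved <- integer(0)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    if (!is.na(occ[i])) {
      new_beads[occ[i], ] <- loop$sites[j, ]
      moved <- c(moved, occ[i])
    }
  }
  affected <- unique((moved - 1L) %/% state$N + 1L)
  new_state <- state
  new_state$beads <- new_beads
  for (c in affected) {
    ch <- get_chain(new_state, c)
    for (b in seq_len(state$N - 1L)) {
      v <- minimum_image(ch[b, ], ch[b + 1L, ], spec)
      if (abs(sum(v^2) - 1) > 1e-9)
        return(list(state = state, accepted = FALSE))
    }
  }
  list(state = new_state, accepted = TRUE)
}

#' Run the cooperative motion engine
#'
#' Advances the system by `n_timesteps` time units using the compiled CMA
#' kernel.  One time unit elapses when the cumulative number of attempted
#' element displacements (tentative walk steps, counted whether or not the
#' walk closes or the move is accepted) reaches the total site count — on
#' average one attempt per element.  At every `measure_every` timesteps the
#' per-chain conformational metrics are recorded; optionally the exact
#' same-chain pair-distance table used by the structure factor is
#' accumulated on every `gamma_every`-th measurement.
#'
#' The engine has its own seeded RNG stream, independent of R's: identical
#' `(state, seed, arguments)` give bitwise-identical trajectories.
#'
#' @param state A `polymer_system`.
#' @param n_timesteps Number of time units to advance.
#' @param seed Engine RNG seed.
#' @param measure_every Timesteps between measurements (0 disables).
#' @param collect_gamma Accumulate the intramolecular pair-distance table.
#' @param gamma_every Collect gamma on every `gamma_every`-th measurement.
#' @param max_len Maximum cooperative-loop length (sites).
#' @return An object of class `cma_run`: list with the final `state`, a
#'   `measurements` data frame (ensemble means of Rg^2, Ree^2, the
#'   gyration-tensor eigenvalues, and the asphericity accumulators per
#'   measurement), `stats` (attempts, closed loops, accepted moves,
#'   attempted displacements, loop-length histogram) and, when requested,
#'   `gamma` (exact integer-r^2 pair counts).
#' @export
cma_run <- function(state, n_timesteps, seed = 1, measure_every = 10L,
                    collect_gamma = FALSE, gamma_every = 4L, max_len = 100L) {
  stopifnot(inherits(state, "polymer_system"), n_timesteps >= 0)
  res <- cma_run_cpp(state$beads, state$spec$edge, state$spec$layers,
                     state$N, state$n_chains, as.numeric(seed),
                     as.numeric(n_timesteps), as.integer(max_len),
                     as.integer(measure_every), as.integer(gamma_every),
                     isTRUE(collect_gamma), as.numeric(state$timestep))
  new_state <- state
  new_state$beads <- res$beads
  colnames(new_state$beads) <- c("a", "b", "layer")
  new_state$timestep <- res$timestep
  meas <- as.data.frame(res$measurements)
  gamma <- NULL
  if (collect_gamma && res$gamma_samples > 0)
    gamma <- new_gamma_profile(res$gamma_counts, res$gamma_samples, state$N)
  structure(list(state = new_state, measurements = meas, gamma = gamma,
                 stats = list(attempts = res$attempts,
                              closed_loops = res$closed_loops,
                              accepted = res$accepted,
                              displacements = res$displacements,
                              loop_hist = res$loop_hist),
                 seed = seed, n_timesteps = n_timesteps),
            class = "cma_run")
}

#' @export
print.cma_run <- function(x, ...) {
  s <- x$stats
  cat(sprintf("CMA run: %g timesteps (now at t = %g), seed %g\n",
              x$n_timesteps, x$state$timestep, x$seed))
  cat(sprintf("  %g proposals, %g closed loops, %g accepted (%.1f%% of proposals)\n",
              s$attempts, s$closed_loops, s$accepted,
              100 * s$accepted / max(1, s$attempts)))
  if (nrow(x$measurements) > 0)
    cat(sprintf("  %d measurements; final <Rg^2> = %.4g, <Ree^2> = %.4g\n",
                nrow(x$measurements),
                mean(x$measurements$rg2_mean),
                mean(x$measurements$ree2_mean)))
  invisible(x)
}

#' Equilibrate a system
#'
#' Runs the engine in windows of `window` timesteps and monitors the block
#' mean of the ensemble `<Rg^2>`.  The system is considered equilibrated
#' when `consecutive` successive windows each agree with their predecessor
#' within `tol_se` combined standard errors of the block means.
#'
#' @param state A `polymer_system`.
#' @param seed Engine RNG seed (window seeds are derived from it).
#' @param window Window width in timesteps.
#' @param tol_se Agreement tolerance in combined standard errors.
#' @param consecutive Number of consecutive agreeing window pairs required.
#' @param max_windows Cap on the number of windows; on hitting the cap a
#'   warning is raised and `converged = FALSE` is returned with the full
#'   window history for diagnosis.
#' @param measure_every Measurement interval inside each window.
#' @param max_len Maximum cooperative-loop length.
#' @return List with `state`, `time` (timesteps elapsed), `converged`, and
#'   `history` (per-window block means and standard errors).
#' @export
equilibrate <- function(state, seed = 1, window = 500L, tol_se = 2,
                        consecutive = 2L, max_windows = 200L,
                        measure_every = max(1L, as.integer(window / 10L)),
                        max_len = 100L) {
  means <- ses <- numeric(0)
  agree <- 0L
  t0 <- state$timestep
  for (w in seq_len(max_windows)) {
    run <- cma_run(state, window, seed = as.numeric(seed) * 1000 + w,
                   measure_every = measure_every, max_len = max_len)
    state <- run$state
    m <- run$measurements$rg2_mean
    means <- c(means, mean(m))
    ses <- c(ses, sd(m) / sqrt(length(m)))
    if (w >= 2L) {
      gap <- abs(means[w] - means[w - 1L])
      if (gap < tol_se * sqrt(ses[w]^2 + ses[w - 1L]^2)) {
        agree <- agree + 1L
        if (agree >= consecutive)
          return(list(state = state, time = state$timestep - t0,
                      converged = TRUE,
                      history = data.frame(window = seq_len(w), mean = means,
                                           se = ses)))
      } else agree <- 0L
    }
  }
  warning("equilibrate: window cap reached without convergence")
  list(state = state, time = state$timestep - t0, converged = FALSE,
       history = data.frame(window = seq_along(means), mean = means, se = ses))
}
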