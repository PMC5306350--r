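#' Unwrap a chain across periodic boundaries
#'
#' Places bead 1 at its in-box Cartesian position and reconstructs every
#' subsequent bead by adding the minimum-image displacement of its bond, so
#' consecutive beads are exactly one bond length apart and the chain is a
#' connected object in unbounded space.
#'
#' @param chain Integer bead matrix (columns `a`, `b`, `layer`) of one
#'   chain, e.g. from a `polymer_system`.
#' @param spec The [lattice_spec()] of the box.
#' @return Numeric matrix of unwrapped Cartesian coordinates (`x`, `y` and,
#'   for two-layer boxes, `z`).
#' @export
unwrap_chain <- function(chain, spec) {
  ax <- unwrap_axial(chain, spec)
  out <- cbind(x = ax[, 1L] + ax[, 2L] / 2, y = ax[, 2L] * sqrt(3) / 2)
  if (spec$layers == 2L) out <- cbind(out, z = ax[, 3L])
  out
}

# unwrapped axial coordinates (ua, ub, ulayer); errors on a broken bond
unwrap_axial <- function(chain, spec) {
  L <- spec$edge
  n <- nrow(chain)
  da <- reduce_axial(diff(chain[, 1L]), L)
  db <- reduce_axial(diff(chain[, 2L]), L)
  dl <- diff(chain[, 3L])
  if (n > 1L) {
    len2 <- ifelse(dl != 0, (da == 0 & db == 0) * dl^2, da^2 + da * db + db^2)
    if (any(len2 != 1))
      stop("broken bond: consecutive beads are not lattice neighbours",
           call. = FALSE)
  }
  cbind(chain[1L, 1L] + c(0, cumsum(da)),
        chain[1L, 2L] + c(0, cumsum(db)),
        chain[1L, 3L] + c(0, cumsum(dl)))
}

#' Squared radius of gyration of a chain
#'
#' Mean squared distance of the unwrapped beads from their centroid.
#'
#' @inheritParams unwrap_chain
#' @return Numeric scalar, in squared lattice (bond-length) units.
#' @export
radius_of_gyration_sq <- function(chain, spec) {
  if (is.null(nrow(chain)) || nrow(chain) < 1L)
    stop("empty chain", call. = FALSE)
  xyz <- unwrap_chain(chain, spec)
  ctr <- colMeans(xyz)
  mean(rowSums(sweep(xyz, 2L, ctr)^2))
}

#' Gyration tensor and its eigenvalues
#'
#' Second-moment tensor of the unwrapped bead positions about the chain's
#' center of mass.  Its trace equals the squared radius of gyration, and
#' its eigenvalues describe the coil shape (equal eigenvalues: isotropic;
#' one zero eigenvalue: collinear).
#'
#' @inheritParams unwrap_chain
#' @return The symmetric tensor (2 x 2, or 3 x 3 for a two-layer box) with
#'   attribute `eigenvalues` (ascending).
#' @seealso [asphericity()]
#' @export
gyration_tensor <- function(chain, spec) {
  xyz <- unwrap_chain(chain, spec)
  ctr <- colMeans(xyz)
  d <- sweep(xyz, 2L, ctr)
  t_mat <- crossprod(d) / nrow(d)
  structure(t_mat, eigenvalues = sort(eigen(t_mat, symmetric = TRUE,
                                            only.values = TRUE)$values))
}

#' @rdname gyration_tensor
#' @export
gyration_eigenvalues <- function(chain, spec) {
  attr(gyration_tensor(chain, spec), "eigenvalues")
}

#' Ensemble asphericity
#'
#' The asphericity is the ratio of ensemble means
#' `A2 = <(lambda2 - lambda1)^2> / <(lambda2 + lambda1)^2>` over the two
#' (dominant) gyration-tensor eigenvalues — a ratio of means, not a mean of
#' ratios.  `A2 = 1` for fully extended (collinear) configurations and
#' `A2 = 0` for isotropic, disk-like ones.
#'
#' @param lambda1,lambda2 Vectors of per-configuration eigenvalue samples
#'   with `lambda1 <= lambda2`.  Alternatively `lambda1` may be a two-column
#'   matrix of samples.
#' @return The asphericity, in `[0, 1]`.
#' @export
asphericity <- function(lambda1, lambda2 = NULL) {
  if (is.null(lambda2)) {
    stopifnot(ncol(lambda1) == 2L)
    lambda2 <- lambda1[, 2L]
    lambda1 <- lambda1[, 1L]
  }
  denom <- mean((lambda2 + lambda1)^2)
  if (denom == 0)
    stop("degenerate ensemble: all eigenvalue sums are zero", call. = FALSE)
  mean((lambda2 - lambda1)^2) / denom
}

#' Squared end-to-end distance of a chain
#' @inheritParams unwrap_chain
#' @return Squared Cartesian distance between the unwrapped first and last
#'   beads.
#' @export
end_to_end_sq <- function(chain, spec) {
  xyz <- unwrap_chain(chain, spec)
  sum((xyz[nrow(xyz), ] - xyz[1L, ])^2)
}

# --- intramolecular correlation -------------------------------------------

# profile holding the exact same-chain ordered-pair counts indexed by the
# integer squared minimum-image distance (exact on this lattice)
new_gamma_profile <- function(counts, n_samples, N, bins = NULL) {
  r2 <- which(counts > 0) - 1L
  structure(list(kind = "gamma", r = sqrt(r2), r2 = r2,
                 weight = counts[r2 + 1L] / (N * n_samples),
                 counts = counts[r2 + 1L],
                 n_samples = n_samples, N = N, bins = bins),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  if (x$kind == "gamma")
    cat(sprintf(
      "Intramolecular correlation: N = %d, %g chain configuration(s), total weight %.6g\n",
      x$N, x$n_samples, sum(x$weight)))
  else
    cat(sprintf("Pair correlation g(r): %d bins, %g configuration(s)\n",
                nrow(x$table), x$n_samples))
  invisible(x)
}

#' Intramolecular site-site correlation function
#'
#' Counts ordered same-chain bead pairs by their minimum-image separation,
#' normalised per chain configuration by `1/N`; the self pair at r = 0 is
#' included, so the total weight is exactly `N`.  Distances are exact
#' (integer squared distances on the triangular lattice) — binning, when
#' requested, is only a reporting view and is never used in the structure
#' factor.
#'
#' @param state A `polymer_system` (all chains contribute) or a single
#'   chain's bead matrix together with `spec`.
#' @param spec Required when `state` is a bare bead matrix.
#' @param bins Optional ascending bin breaks for a binned report.
#' @return A `correlation_profile` with the exact distance table (`r`,
#'   `weight`) and, when `bins` is given, a binned data frame in `$table`.
#' @export
intramolecular_correlation <- function(state, spec = NULL, bins = NULL) {
  if (inherits(state, "polymer_system")) {
    res <- gamma_counts_cpp(state$beads, state$spec$edge, state$spec$layers,
                            state$N, state$n_chains)
    prof <- new_gamma_profile(res$counts, res$samples, state$N)
  } else {
    stopifnot(inherits(spec, "lattice_spec"))
    n <- nrow(state)
    counts <- numeric(spec$edge^2 + 2L)
    counts[1L] <- n
    if (n > 1L) {
      for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
        r2 <- min_image_r2_cpp(state[i, 1L], state[i, 2L], state[i, 3L],
                               state[j, 1L], state[j, 2L], state[j, 3L],
                               spec$edge)
        counts[r2 + 1L] <- counts[r2 + 1L] + 2
      }
    }
    prof <- new_gamma_profile(counts, 1, n)
  }
  if (!is.null(bins)) {
    idx <- findInterval(prof$r, bins, rightmost.closed = TRUE)
    keep <- idx >= 1L & idx < length(bins)
    prof$bins <- bins
    prof$table <- data.frame(
      bin_lo = bins[-length(bins)], bin_hi = bins[-1L],
      gamma = as.numeric(tapply(prof$weight[keep], factor(idx[keep],
               levels = seq_len(length(bins) - 1L)), sum, default = 0)),
      pairs = as.numeric(tapply(prof$counts[keep], factor(idx[keep],
               levels = seq_len(length(bins) - 1L)), sum, default = 0)))
  }
  prof
}

#' Single-chain static structure factor
#'
#' Evaluates `S(q) = sum_r w(r) sin(qr)/(qr)` over the exact intramolecular
#' pair-distance table, the self term contributing 1 per bead, so
#' `S(q -> 0) -> N`.  The spherically averaged `sin(qr)/(qr)` kernel is the
#' convention used throughout; a strictly two-dimensional isotropic average
#' (Bessel `J0(qr)` kernel) is available for sensitivity checks.
#'
#' @param profile A `correlation_profile` from
#'   [intramolecular_correlation()] or a gamma-collecting [cma_run()].
#' @param q Positive scattering-vector grid (inverse lattice units).
#'   Default: 64 log-spaced points in `[2*pi/L_ref, pi]` with `L_ref = 64`.
#' @param kernel `"sinc"` (default) or `"bessel"`.
#' @return Object of class `structure_factor`: data frame with columns `q`
#'   and `S`.
#' @export
structure_factor <- function(profile, q = NULL, kernel = c("sinc", "bessel")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(profile, "correlation_profile"), profile$kind == "gamma")
  if (is.null(q)) q <- exp(seq(log(2 * pi / 64), log(pi), length.out = 64L))
  if (any(q <= 0)) stop("q must be positive", call. = FALSE)
  r <- profile$r
  w <- profile$weight
  S <- vapply(q, function(qi) {
    k <- ifelse(r == 0, 1,
                if (kernel == "sinc") sin(qi * r) / (qi * r)
                else besselJ(qi * r, 0))
    sum(w * k)
  }, numeric(1L))
  structure(data.frame(q = q, S = S),
            class = c("structure_factor", "data.frame"),
            N = profile$N, kernel = kernel)
}

#' @export
plot.structure_factor <- function(x, ...) {
  graphics::plot(x$q, x$S, log = "xy", type = "l", xlab = "q",
                 ylab = "S(q)", ...)
  invisible(x)
}

# --- center-of-mass pair correlation --------------------------------------

# centers of mass in axial coordinates, wrapped back into the box
cm_axial <- function(state) {
  t(vapply(seq_len(state$n_chains), function(i) {
    ax <- unwrap_axial(get_chain(state, i), state$spec)
    colMeans(ax)[1:2] %% state$spec$edge
  }, numeric(2L)))
}

# pairwise minimum-image distances between axial points (fractional allowed)
axial_pair_dists <- function(pts, L) {
  n <- nrow(pts)
  da0 <- outer(pts[, 1L], pts[, 1L], "-") %% L
  db0 <- outer(pts[, 2L], pts[, 2L], "-") %% L
  best <- matrix(Inf, n, n)
  for (m in c(-L, 0, L)) for (k in c(-L, 0, L)) {
    da <- da0 + m; db <- db0 + k
    r2 <- (da + db / 2)^2 + 0.75 * db^2
    best <- pmin(best, r2)
  }
  sqrt(best[upper.tri(best)])
}

g_from_points <- function(point_sets, L, bins) {
  if (is.null(bins)) bins <- seq(0, floor(L / 2), by = 0.5)
  counts <- numeric(length(bins) - 1L)
  n_pairs <- 0
  for (pts in point_sets) {
    d <- axial_pair_dists(pts, L)
    n_pairs <- n_pairs + length(d)
    idx <- findInterval(d, bins, rightmost.closed = TRUE)
    keep <- idx >= 1L & idx < length(bins)
    counts <- counts + tabulate(idx[keep], nbins = length(bins) - 1L)
  }
  area_box <- L^2 * sqrt(3) / 2
  area_bin <- pi * (bins[-1L]^2 - bins[-length(bins)]^2)
  g <- (counts / n_pairs) / (area_bin / area_box)
  structure(list(kind = "g_cm",
                 table = data.frame(bin_lo = bins[-length(bins)],
                                    bin_hi = bins[-1L],
                                    r = (bins[-1L] + bins[-length(bins)]) / 2,
                                    g = g, pairs = counts),
                 n_samples = length(point_sets), n_pairs = n_pairs),
            class = "correlation_profile")
}

#' Center-of-mass pair correlation function
#'
#' Histogram of minimum-image distances between the centers of mass of
#' distinct chains, normalised by the annulus area so that an uncorrelated
#' (ideal-gas) arrangement gives `g(r) = 1` at every `r`; a correlation
#' hole appears as `g(r) < 1` at small `r`.  Centers of mass are computed
#' from unwrapped coordinates and mapped back into the box.  Single-layer
#' boxes only.
#'
#' @param states A `polymer_system` with at least two chains, or a list of
#'   such systems (configurations of the same ensemble).
#' @param bins Ascending distance bin breaks; default `0` to `L/2` in steps
#'   of `0.5`.
#' @return A `correlation_profile` with `$table` columns `r` and `g`.
#' @export
cm_pair_correlation <- function(states, bins = NULL) {
  if (inherits(states, "polymer_system")) states <- list(states)
  s1 <- states[[1L]]
  if (s1$n_chains < 2L)
    stop("cm_pair_correlation needs at least 2 chains", call. = FALSE)
  if (s1$spec$layers != 1L)
    stop("cm_pair_correlation supports single-layer boxes", call. = FALSE)
  g_from_points(lapply(states, cm_axial), s1$spec$edge, bins)
}

#' Pair correlation of a point pattern on the lattice
#'
#' Same estimator as [cm_pair_correlation()] for an arbitrary set of sites
#' (used with the uniform-points fixture to verify the plateau-1
#' normalisation).
#'
#' @param points Matrix of axial coordinates (columns `a`, `b`), or a list
#'   of such matrices.
#' @param spec A [lattice_spec()].
#' @param bins As in [cm_pair_correlation()].
#' @return A `correlation_profile`.
#' @export
point_pair_correlation <- function(points, spec, bins = NULL) {
  if (!is.list(points)) points <- list(points)
  g_from_points(points, spec$edge, bins)
}

# --- solvent domains -------------------------------------------------------

# neighbour table for all sites (n_sites x coordination), 1-based indices
neighbor_table <- function(spec) {
  L <- spec$edge
  n <- spec$n_sites
  s <- 0:(n - 1L)
  a <- s %% L
  b <- (s %/% L) %% L
  l <- s %/% (L * L)
  uv <- unit_vectors()
  nbr <- matrix(0L, n, spec$coordination)
  for (d in 1:6)
    nbr[, d] <- 1L + (a + uv[d, 1L]) %% L + L * ((b + uv[d, 2L]) %% L) + L * L * l
  if (spec$layers == 2L) nbr[, 7L] <- 1L + a + L * b + L * L * (1L - l)
  nbr
}

#' Connected solvent domain sizes
#'
#' Sizes of the connected components of solvent sites under lattice
#' adjacency.  Large solvent domains signal the transient microphase
#' separation seen at intermediate concentrations in strictly 2D systems.
#'
#' @param state A `polymer_system` with `phi < 1`.
#' @return Integer vector of component sizes (sums to the solvent site
#'   count); empty for a melt.
#' @export
solvent_cluster_sizes <- function(state) {
  occ <- occupancy(state)
  solvent <- which(occ == 0L)
  if (length(solvent) == 0L) return(integer(0))
  nbr <- neighbor_table(state$spec)
  lab <- integer(state$spec$n_sites)  # 0 = unvisited solvent or polymer
  lab[occ != 0L] <- -1L
  sizes <- integer(0)
  comp <- 0L
  stack <- integer(length(solvent))
  for (s0 in solvent) {
    if (lab[s0] != 0L) next
    comp <- comp + 1L
    size <- 0L
    top <- 1L
    stack[1L] <- s0
    lab[s0] <- comp
    while (top > 0L) {
      s <- stack[top]; top <- top - 1L
      size <- size + 1L
      for (nb in nbr[s, ]) {
        if (lab[nb] == 0L) {
          lab[nb] <- comp
          top <- top + 1L
          stack[top] <- nb
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}
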