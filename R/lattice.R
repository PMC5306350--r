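#' Triangular-lattice box specification
#'
#' Defines a periodic simulation box on the 2D triangular lattice: a rhombic
#' cell of `edge` x `edge` sites spanned by the axial directions, optionally
#' doubled into two stacked layers (quasi-2D).  Axial coordinates `(a, b)`
#' map to Cartesian positions `x = a + b/2`, `y = b*sqrt(3)/2` so every bond
#' between nearest neighbours has unit length; the two-layer variant adds
#' `z = layer` with interlayer spacing 1.
#'
#' @param edge Number of sites per side, `L >= 4`.
#' @param layers 1 (strictly 2D) or 2 (quasi-2D, two stacked layers).
#'
#' @return An object of class `lattice_spec` with fields `edge`, `layers`,
#'   `n_sites` and `coordination` (6 in-plane neighbours, plus the mirror
#'   site in the other layer when `layers = 2`).
#' @examples
#' spec <- lattice_spec(8)
#' neighbors(c(0, 0), spec)
#' @export
lattice_spec <- function(edge, layers = 1L) {
  edge <- as.integer(edge)
  layers <- as.integer(layers)
  if (length(edge) != 1L || is.na(edge) || edge < 4L)
    stop("edge must be a single integer >= 4", call. = FALSE)
  if (length(layers) != 1L || is.na(layers) || !layers %in% c(1L, 2L))
    stop("layers must be 1 or 2", call. = FALSE)
  structure(list(edge = edge, layers = layers,
                 n_sites = layers * edge^2,
                 coordination = if (layers == 2L) 7L else 6L),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("Triangular lattice box: L = %d, layers = %d (%d sites, coordination %d)\n",
              x$edge, x$layers, x$n_sites, x$coordination))
  invisible(x)
}

# the six in-layer unit displacement vectors (axial coordinates)
unit_vectors <- function() {
  matrix(c(1L, 0L, -1L, 0L, 0L, 1L, 0L, -1L, 1L, -1L, -1L, 1L),
         ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("da", "db")))
}

as_site <- function(site) {
  site <- as.integer(site)
  if (length(site) == 2L) site <- c(site, 0L)
  if (length(site) != 3L || anyNA(site))
    stop("a site is an integer vector (a, b) or (a, b, layer)", call. = FALSE)
  names(site) <- c("a", "b", "layer")
  site
}

check_site <- function(site, spec) {
  site <- as_site(site)
  if (site[["a"]] < 0L || site[["a"]] >= spec$edge ||
      site[["b"]] < 0L || site[["b"]] >= spec$edge)
    stop("site coordinates out of range [0, L)", call. = FALSE)
  if (site[["layer"]] < 0L || site[["layer"]] >= spec$layers)
    stop("site layer out of range for this box", call. = FALSE)
  site
}

#' Nearest neighbours of a lattice site
#'
#' Each site has the six in-layer neighbours of the triangular lattice,
#' periodic-wrapped in both axial directions; in a two-layer box the mirror
#' site directly above/below is the seventh neighbour.
#'
#' @param site Integer vector `(a, b)` or `(a, b, layer)`.
#' @param spec A [lattice_spec()].
#' @return Integer matrix with columns `a`, `b`, `layer`, one row per
#'   neighbour (6 rows for `layers = 1`, 7 for `layers = 2`).
#' @export
neighbors <- function(site, spec) {
  site <- check_site(site, spec)
  uv <- unit_vectors()
  L <- spec$edge
  nb <- cbind(a = (site[["a"]] + uv[, 1L]) %% L,
              b = (site[["b"]] + uv[, 2L]) %% L,
              layer = rep(site[["layer"]], 6L))
  if (spec$layers == 2L)
    nb <- rbind(nb, c(site[["a"]], site[["b"]], 1L - site[["layer"]]))
  storage.mode(nb) <- "integer"
  rownames(nb) <- NULL
  nb
}

#' Cartesian embedding of lattice sites
#'
#' Maps axial coordinates to the unit-bond Cartesian embedding
#' `x = a + b/2`, `y = b*sqrt(3)/2` (and `z = layer` for two-layer sites).
#'
#' @param sites Integer vector for one site, or a matrix with columns
#'   `a`, `b` and optionally `layer`.
#' @return Numeric matrix with columns `x`, `y` (and `z` when any site lies
#'   outside layer 0 or a `layer` column is present with 2 layers in use).
#' @export
to_cartesian <- function(sites) {
  if (is.null(dim(sites))) sites <- matrix(as_site(sites), nrow = 1L,
                                           dimnames = list(NULL, c("a", "b", "layer")))
  a <- sites[, 1L]; b <- sites[, 2L]
  layer <- if (ncol(sites) >= 3L) sites[, 3L] else rep(0, nrow(sites))
  out <- cbind(x = a + b / 2, y = b * sqrt(3) / 2)
  if (any(layer != 0)) out <- cbind(out, z = as.numeric(layer))
  out
}

# reduce an axial delta to the representative in (-L/2, L/2]
reduce_axial <- function(d, L) {
  d <- d %% L
  d - L * (d > L / 2)
}

#' Minimum-image displacement between two sites
#'
#' Returns the shortest Cartesian displacement from `s1` to `s2` over the
#' nine periodic images of the rhombic cell (27 including the layer offset
#' is unnecessary: layers do not wrap).
#'
#' @param s1,s2 Sites as integer vectors `(a, b[, layer])`.
#' @param spec A [lattice_spec()].
#' @return Numeric vector `(x, y[, z])`; its Euclidean length is the
#'   minimum-image distance.
#' @export
minimum_image <- function(s1, s2, spec) {
  s1 <- check_site(s1, spec); s2 <- check_site(s2, spec)
  L <- spec$edge
  da0 <- (s2[["a"]] - s1[["a"]]) %% L
  db0 <- (s2[["b"]] - s1[["b"]]) %% L
  best <- NULL; best_r2 <- Inf
  for (m in -1:1) for (n in -1:1) {
    da <- da0 + m * L; db <- db0 + n * L
    x <- da + db / 2; y <- db * sqrt(3) / 2
    r2 <- x^2 + y^2
    if (r2 < best_r2) { best_r2 <- r2; best <- c(x = x, y = y) }
  }
  if (spec$layers == 2L) best <- c(best, z = s2[["layer"]] - s1[["layer"]])
  best
}

#' Minimum-image distance between two sites
#' @inheritParams minimum_image
#' @return The minimum-image Euclidean distance.
#' @export
minimum_image_distance <- function(s1, s2, spec) {
  sqrt(sum(minimum_image(s1, s2, spec)^2))
}

#' Off-lattice concentration convention conversion
#'
#' Site-fraction concentrations on a lattice can be compared with
#' area-fraction conventions used in off-lattice work, where the maximum
#' packing of equal discs is the close-packing fraction `pi / (2*sqrt(3))`,
#' about 0.9069.  `close_packing_fraction()` returns that constant;
#' `phi_area()` rescales a site fraction onto the disc-area scale.
#'
#' @param phi Site-fraction concentration in `[0, 1]`.
#' @return `close_packing_fraction()` returns `pi/(2*sqrt(3))`;
#'   `phi_area(phi)` returns `phi * pi/(2*sqrt(3))`.
#' @export
close_packing_fraction <- function() pi / (2 * sqrt(3))

#' @rdname close_packing_fraction
#' @export
phi_area <- function(phi) {
  stopifnot(all(phi >= 0 & phi <= 1))
  phi * close_packing_fraction()
}
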