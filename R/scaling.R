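#' Fit a power law by log-log least squares
#'
#' Ordinary least-squares fit of `log(y) ~ log(x)` restricted to a window
#' of the abscissa.  This is the workhorse behind the chain-length scaling
#' exponent, the concentration exponent and the structure-factor fractal
#' slope.
#'
#' @param x,y Positive numeric vectors.
#' @param window Length-2 abscissa range to fit within (inclusive).
#' @param kind Label describing what the exponent is (carried in the
#'   object, e.g. `"2nu"`, `"concentration"`, `"sq-slope"`).
#' @return Object of class `scaling_fit` with fields `exponent`, `stderr`,
#'   `prefactor`, `window`, `r_squared`, `kind`, `n`, and the underlying
#'   `lm` fit.  Standard S3 methods `print`, `summary`, `coef`, `predict`
#'   and `confint` are provided.
#' @examples
#' f <- fit_power_law(c(16, 32, 64), 0.2 * c(16, 32, 64)^1.5)
#' coef(f)
#' @export
fit_power_law <- function(x, y, window = range(x), kind = "generic") {
  keep <- x >= window[1L] & x <= window[2L] & is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("need at least 3 points inside the fit window", call. = FALSE)
  if (any(x <= 0) || any(y <= 0))
    stop("power-law fit requires positive data", call. = FALSE)
  df <- data.frame(lx = log(x), ly = log(y))
  fit <- lm(ly ~ lx, data = df)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a benign warning
  structure(list(exponent = unname(coef(fit)[2L]),
                 stderr = unname(sm$coefficients[2L, 2L]),
                 prefactor = exp(unname(coef(fit)[1L])),
                 window = window, r_squared = sm$r.squared,
                 kind = kind, n = length(x), model = fit),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (%s): exponent = %.4f +/- %.4f  (R^2 = %.4f, n = %d)\n",
              x$kind, x$exponent, x$stderr, x$r_squared, x$n))
  cat(sprintf("  window [%g, %g], prefactor %.4g\n",
              x$window[1L], x$window[2L], x$prefactor))
  invisible(x)
}

#' @export
summary.scaling_fit <- function(object, ...) {
  out <- c(exponent = object$exponent, stderr = object$stderr,
           prefactor = object$prefactor, r_squared = object$r_squared,
           n = object$n)
  print(object)
  invisible(out)
}

#' @export
coef.scaling_fit <- function(object, ...) {
  c(prefactor = object$prefactor, exponent = object$exponent)
}

#' @export
predict.scaling_fit <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$x else newdata
  object$prefactor * x^object$exponent
}

#' @export
confint.scaling_fit <- function(object, parm = "exponent", level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  object$exponent + c(-1, 1) * z * object$stderr
}

#' Chain-length scaling exponent 2nu
#'
#' Fits `<Rg^2> ~ N^(2nu)` over a table of chain lengths.  In 2D, `2nu` is
#' 3/2 for dilute chains in good (athermal) solvent and 1 for ideal chains
#' or chains in a melt.
#'
#' @param N Chain lengths.
#' @param rg2 Corresponding mean squared radii of gyration.
#' @param window Fit window on `N` (default: all lengths).
#' @return A `scaling_fit` with `kind = "2nu"`.
#' @export
estimate_2nu <- function(N, rg2, window = range(N)) {
  fit_power_law(N, rg2, window, kind = "2nu")
}

#' Concentration scaling of chain size
#'
#' Fits `<Rg^2> ~ phi^x` in the concentrated regime at fixed chain length.
#' The blob-scaling reference value is
#' `x = (1 - 2*nu) / (d*nu - 1)`, which equals -1 for excluded-volume
#' chains (`nu = 3/4`) in `d = 2`, and 0 for ideal chains in `d = 3`
#' (concentration then has no effect).
#'
#' @param phi Concentrations (all in the concentrated regime).
#' @param rg2 Mean squared radii of gyration at those concentrations.
#' @param window Fit window on `phi`.
#' @return A `scaling_fit` with `kind = "concentration"`.
#' @export
estimate_concentration_exponent <- function(phi, rg2, window = range(phi)) {
  fit_power_law(phi, rg2, window, kind = "concentration")
}

#' @rdname estimate_concentration_exponent
#' @param nu Flory exponent.
#' @param d Spatial dimension.
#' @return `concentration_exponent_reference` returns the analytic exponent
#'   `(1 - 2*nu)/(d*nu - 1)`.
#' @export
concentration_exponent_reference <- function(nu, d) {
  (1 - 2 * nu) / (d * nu - 1)
}

#' Fractal slope of the structure factor
#'
#' Log-log slope of `S(q)` inside the fractal window
#' `2*pi/Rg << q << 2*pi` (well below the Guinier knee, well above the
#' monomer scale).  The slope estimates `-1/nu`: -4/3 for dilute 2D
#' excluded-volume chains, -2 for ideal/melt chains.
#'
#' @param curve A `structure_factor` (or any data frame with columns `q`
#'   and `S`).
#' @param window Length-2 `q` window to fit in.
#' @return A `scaling_fit` with `kind = "sq-slope"`.
#' @export
sq_slope <- function(curve, window = range(curve$q)) {
  fit_power_law(curve$q, curve$S, window, kind = "sq-slope")
}

#' Detect a blob crossover in the structure factor
#'
#' Fits a two-segment piecewise-linear model in log-log coordinates; the
#' breakpoint `q*` is chosen on the discrete `q` grid by minimising the
#' total squared error, and the correlation length is `xi = 2*pi/q*`.
#' When the two segment slopes differ by less than `delta_threshold`, the
#' curve is declared a single power law (`crossover = FALSE`) — that is a
#' regular result, not an error.
#'
#' @param curve A `structure_factor` (>= 12 grid points).
#' @param min_segment Minimum points per segment.
#' @param delta_threshold Minimum absolute slope difference for a
#'   crossover call.
#' @return Object of class `crossover_estimate`: `q_star`, `xi`,
#'   `slope_low` (slope of the low-q segment), `slope_high`, `crossover`.
#' @export
detect_crossover <- function(curve, min_segment = 4L, delta_threshold = 0.25) {
  q <- curve$q; S <- curve$S
  stopifnot(length(q) >= 12L)
  lx <- log(q); ly <- log(S)
  n <- length(q)
  best <- list(sse = Inf)
  for (k in (min_segment):(n - min_segment)) {
    i1 <- 1:k; i2 <- (k + 1L):n
    f1 <- lm(ly[i1] ~ lx[i1]); f2 <- lm(ly[i2] ~ lx[i2])
    sse <- sum(f1$residuals^2) + sum(f2$residuals^2)
    if (sse < best$sse)
      best <- list(sse = sse, k = k,
                   slope_low = unname(coef(f1)[2L]),
                   slope_high = unname(coef(f2)[2L]))
  }
  q_star <- sqrt(q[best$k] * q[best$k + 1L])  # break between grid points
  crossover <- abs(best$slope_high - best$slope_low) >= delta_threshold
  structure(list(q_star = if (crossover) q_star else NA_real_,
                 xi = if (crossover) 2 * pi / q_star else NA_real_,
                 slope_low = best$slope_low, slope_high = best$slope_high,
                 crossover = crossover, sse = best$sse),
            class = "crossover_estimate")
}

#' @export
print.crossover_estimate <- function(x, ...) {
  if (x$crossover)
    cat(sprintf("Crossover at q* = %.4g (xi = %.4g): slope %.3f (low q) -> %.3f (high q)\n",
                x$q_star, x$xi, x$slope_low, x$slope_high))
  else
    cat(sprintf("No crossover: slopes %.3f / %.3f within threshold\n",
                x$slope_low, x$slope_high))
  invisible(x)
}
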