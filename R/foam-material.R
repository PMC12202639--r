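# Quasi-static point model of a low-density seat foam: piecewise-linear
# compressive loading curve plus a hysteretic unloading branch governed
# by the unloading coefficient HU and the shape factor SHAPE, and
# least-squares identification of (HU, SHAPE) from load-unload tests.
#
# Unloading model: sigma_u(eps) = sigma_l(eps) * [hu + (1 - hu) *
# (W(eps)/W(eps_max))^shape], with W the strain-energy density of the
# loading curve. This is a documented phenomenological form: it is
# continuous at the reversal point, collapses to the loading curve at
# hu = 1, and never exceeds it for hu <= 1. The creep decay constant
# BETA is carried in foam_params but plays no role quasi-statically.

.check_curve <- function(load_curve) {
  if (inherits(load_curve, "foam_params")) return(load_curve$load_curve)
  lc <- as.matrix(load_curve)
  if (ncol(lc) != 2L || nrow(lc) < 2L)
    stop("load_curve must be an n x 2 (strain, stress) matrix")
  if (any(diff(lc[, 1L]) <= 0)) stop("load_curve strains must increase")
  if (any(diff(lc[, 2L]) < 0)) stop("load_curve stresses must be non-decreasing")
  if (abs(lc[1L, 1L]) > 1e-12 || abs(lc[1L, 2L]) > 1e-12)
    stop("load_curve must start at (0, 0)")
  lc
}

#' Loading-branch stress
#'
#' Piecewise-linear interpolation of the monotone compressive loading
#' curve. Strains outside the curve domain raise an error; the model
#' never extrapolates silently.
#'
#' @param strain Engineering strain(s), within the curve domain.
#' @param load_curve n x 2 (strain, stress MPa) matrix or a
#'   [foam_params()].
#' @return Stress in MPa, vectorized over `strain`.
#' @export
loading_stress <- function(strain, load_curve) {
  lc <- .check_curve(load_curve)
  strain <- as.numeric(strain)
  lo <- lc[1L, 1L]; hi <- lc[nrow(lc), 1L]
  if (any(strain < lo - 1e-12) || any(strain > hi + 1e-12))
    stop("loading_stress: strain ", strain[which(strain < lo - 1e-12 |
                                                 strain > hi + 1e-12)][1L],
         " outside the load curve domain [", lo, ", ", hi, "]")
  strain <- pmin(pmax(strain, lo), hi)
  stats::approx(lc[, 1L], lc[, 2L], xout = strain, method = "linear",
                ties = "ordered")$y
}

# strain-energy density W(eps) = int_0^eps sigma_l, exact for the
# piecewise-linear curve (piecewise quadratic in eps)
.load_energy <- function(strain, lc) {
  eps_k <- lc[, 1L]; sig_k <- lc[, 2L]
  Wk <- c(0, cumsum(diff(eps_k) * (utils::head(sig_k, -1L) +
                                   utils::tail(sig_k, -1L)) / 2))
  seg <- findInterval(strain, eps_k, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), length(eps_k) - 1L)
  de <- strain - eps_k[seg]
  slope <- (sig_k[seg + 1L] - sig_k[seg]) / (eps_k[seg + 1L] - eps_k[seg])
  Wk[seg] + sig_k[seg] * de + 0.5 * slope * de^2
}

#' Unloading-branch stress of the hysteretic foam model
#'
#' @param strain Engineering strain(s), in `[0, eps_max]`.
#' @param eps_max Strain at load reversal (> 0, within curve domain).
#' @param load_curve n x 2 (strain, stress) matrix or [foam_params()].
#' @param hu Hysteretic unloading coefficient in (0, 1].
#' @param shape Unloading shape factor > 0.
#' @return Stress in MPa, vectorized over `strain`.
#' @export
unloading_stress <- function(strain, eps_max, load_curve, hu, shape) {
  lc <- .check_curve(load_curve)
  if (inherits(load_curve, "foam_params")) {
    if (missing(hu)) hu <- load_curve$hu
    if (missing(shape)) shape <- load_curve$shape
  }
  if (!is.finite(hu) || hu <= 0 || hu > 1) stop("unloading_stress: hu must be in (0, 1]")
  if (!is.finite(shape) || shape <= 0) stop("unloading_stress: shape must be > 0")
  if (!is.finite(eps_max) || eps_max <= 0)
    stop("unloading_stress: degenerate load history (eps_max must be > 0)")
  strain <- as.numeric(strain)
  if (any(strain < -1e-12) || any(strain > eps_max + 1e-12))
    stop("unloading_stress: strain outside [0, eps_max]")
  strain <- pmin(pmax(strain, 0), eps_max)
  w_max <- .load_energy(eps_max, lc)
  if (w_max <= 0)
    stop("unloading_stress: zero strain energy at eps_max (degenerate curve)")
  ratio <- .load_energy(strain, lc) / w_max
  loading_stress(strain, lc) * (hu + (1 - hu) * ratio^shape)
}

#' Energy dissipated over one load-unload cycle
#'
#' Area enclosed by the hysteresis loop, in MPa (energy density per
#' cycle). For a measured [uniaxial_test()] the loop area is the
#' trapezoidal path integral of the cycle; for model parameters it is
#' the integral of the loading-unloading stress gap on a fine strain
#' grid. Zero iff `hu = 1`.
#'
#' @param test A [uniaxial_test()] covering a full cycle (unloading
#'   back to (near) zero strain), or `NULL` to use model parameters.
#' @param load_curve,hu,shape,eps_max Model route (used when `test` is
#'   `NULL`).
#' @param n Grid size for the model-route quadrature.
#' @return Dissipated energy density (MPa), >= 0 up to quadrature and
#'   measurement noise.
#' @export
dissipated_energy <- function(test = NULL, load_curve = NULL, hu = NULL,
                              shape = NULL, eps_max = NULL, n = 4096L) {
  if (!is.null(test)) {
    stopifnot(inherits(test, "uniaxial_test"))
    e <- test$strain; s <- test$stress
    emax <- e[test$i_max]
    if (test$i_max == length(e) || min(e[test$i_max:length(e)]) > 0.01 * emax)
      stop("dissipated_energy: incomplete cycle (unloading branch must ",
           "return to (near) zero strain)")
    # signed path integral of sigma d eps over the closed loop:
    # positive over loading (d eps > 0), negative over unloading
    return(sum(diff(e) * (utils::head(s, -1L) + utils::tail(s, -1L)) / 2))
  }
  lc <- .check_curve(load_curve)
  eps <- seq(0, eps_max, length.out = n)
  gap <- loading_stress(eps, lc) - unloading_stress(eps, eps_max, lc, hu, shape)
  sum(diff(eps) * (utils::head(gap, -1L) + utils::tail(gap, -1L)) / 2)
}

#' Identify HU and SHAPE from load-unload tests
#'
#' Bounded least-squares fit of the hysteretic unloading parameters to
#' the unloading-branch samples of one or more tests, given the
#' loading curve. The objective is the sum of squared stress residuals
#' over all unloading samples. A fixed-seed multi-start (L-BFGS-B from
#' `n_starts` points spread over the bounds) guards against local
#' minima of the SHAPE nonlinearity.
#'
#' @param tests A [uniaxial_test()] or list of them; each needs an
#'   unloading branch.
#' @param load_curve n x 2 (strain, stress) matrix or [foam_params()].
#' @param bounds List with `hu` and `shape` length-2 ranges.
#' @param n_starts Number of optimizer starts (>= 1).
#' @param seed Integer seed for the start-point draw.
#' @return List of class `foam_fit`: `hu`, `shape`, `residual_norm`
#'   (RMS of residuals), `objective` (sum of squares), `converged`,
#'   `n_obs`.
#' @export
fit_foam_params <- function(tests, load_curve,
                            bounds = list(hu = c(1e-3, 1), shape = c(0.05, 10)),
                            n_starts = 8L, seed = 1L) {
  if (inherits(tests, "uniaxial_test")) tests <- list(tests)
  lc <- .check_curve(load_curve)
  obs <- lapply(tests, function(tst) {
    stopifnot(inherits(tst, "uniaxial_test"))
    if (tst$i_max >= length(tst$strain))
      stop("fit_foam_params: a test has no unloading branch")
    i <- tst$i_max:length(tst$strain)
    list(strain = tst$strain[i], stress = tst$stress[i],
         eps_max = tst$strain[tst$i_max])
  })
  n_obs <- sum(lengths(lapply(obs, `[[`, "strain")))
  objective <- function(par) {
    hu <- par[1L]; shape <- par[2L]
    sum(vapply(obs, function(o) {
      pred <- unloading_stress(o$strain, o$eps_max, lc, hu, shape)
      sum((o$stress - pred)^2)
    }, numeric(1)))
  }
  starts <- .with_seed(seed, {
    rbind(c(0.5, 1),
          if (n_starts > 1L)
            cbind(stats::runif(n_starts - 1L, bounds$hu[1L], bounds$hu[2L]),
                  stats::runif(n_starts - 1L, bounds$shape[1L], bounds$shape[2L])))
  })
  best <- NULL
  any_conv <- FALSE
  for (k in seq_len(nrow(starts))) {
    fit <- try(stats::optim(starts[k, ], objective, method = "L-BFGS-B",
                            lower = c(bounds$hu[1L], bounds$shape[1L]),
                            upper = c(bounds$hu[2L], bounds$shape[2L]),
                            control = list(factr = 1e4)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("fit_foam_params: all optimizer starts failed")
  structure(list(hu = unname(best$par[1L]), shape = unname(best$par[2L]),
                 objective = best$value,
                 residual_norm = sqrt(best$value / n_obs),
                 converged = any_conv, n_obs = n_obs),
            class = "foam_fit")
}

#' @export
print.foam_fit <- function(x, ...) {
  cat(sprintf("foam_fit: HU = %.4f, SHAPE = %.4f (RMS residual %.3g MPa, %d obs%s)\n",
              x$hu, x$shape, x$residual_norm, x$n_obs,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
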