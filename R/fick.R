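#' Corn-grain geometry
#'
#' The grain is treated as a homogeneous sphere of radius `radius_a` for the
#' diffusion analysis. The default, 0.0049 m, is the average radius of a
#' white corn grain.
#'
#' @param radius_a Sphere radius, meters, `> 0`.
#' @return An object of class `grain_geometry`.
#' @export
grain_geometry <- function(radius_a = 0.0049) {
  stopifnot(is.numeric(radius_a), length(radius_a) == 1L, is.finite(radius_a))
  if (radius_a <= 0) stop("`radius_a` must be > 0 meters; got ", radius_a)
  structure(list(radius_a = radius_a), class = "grain_geometry")
}

as_grain_geometry <- function(x) {
  if (inherits(x, "grain_geometry")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(grain_geometry(x))
  stop("cannot interpret object as grain geometry")
}

#' Sphere-geometry moisture ratio from Fick's second law
#'
#' Series solution for diffusion out of a sphere of radius \eqn{a} with
#' uniform initial concentration and constant surface concentration:
#' \deqn{MR(t) = \frac{6}{\pi^2}\sum_{n=1}^{\infty} \frac{1}{n^2}
#'   \exp\!\left(-\frac{D_{eff}\, n^2 \pi^2 t}{a^2}\right).}
#' At `t = 0` the Basel sum \eqn{\sum 1/n^2 = \pi^2/6} normalizes the value
#' to 1. The series is truncated at `n_terms` terms, with an early exit once
#' a term's magnitude drops below `tol`.
#'
#' @param deff Effective diffusivity, m\eqn{^2} per minute, `> 0`
#'   (`deff = 0` is accepted and returns 1: no diffusion).
#' @param geom A [grain_geometry()] object (or a bare radius in meters).
#' @param t Drying time(s), minutes, `>= 0`. Vectorized.
#' @param n_terms Maximum number of series terms, `>= 1`.
#' @param tol Early-exit threshold on a term's magnitude.
#' @return Moisture ratio in `[0, 1]`, same length as `t`.
#' @seealso [one_term_mr()] for the long-time one-term reduction.
#' @export
fick_series_mr <- function(deff, geom = grain_geometry(), t,
                           n_terms = 200L, tol = 1e-12) {
  g <- as_grain_geometry(geom)
  t <- check_time(t)
  stopifnot(is.numeric(deff), length(deff) == 1L, deff >= 0)
  if (n_terms < 1) stop("`n_terms` must be >= 1; got ", n_terms)
  fo <- deff * pi^2 * t / g$radius_a^2  # dimensionless Fourier number x pi^2
  out <- numeric(length(t))
  pos <- fo > 0
  if (any(pos)) {
    fp <- fo[pos]
    acc <- numeric(length(fp))
    for (n in seq_len(n_terms)) {
      term <- exp(-n^2 * fp) / n^2
      acc <- acc + term
      if (max(term) < tol) break
    }
    out[pos] <- (6 / pi^2) * acc
  }
  # at fo = 0 the full series is the Basel sum: MR is exactly 1; evaluating
  # the analytic limit avoids the slow O(1/N) truncation error there
  out[!pos] <- 1
  out
}

#' One-term reduction of the Fick sphere series
#'
#' Keeping only the `n = 1` term:
#' \eqn{MR(t) \approx (6/\pi^2) \exp(-D_{eff}\pi^2 t / a^2)}.
#' Its logarithm is affine in `t` with slope \eqn{-D_{eff}\pi^2/a^2 = -k},
#' which is what makes the log-linear slope method and the
#' \eqn{k \leftrightarrow D_{eff}} bridge work. Accurate to better than
#' 0.5\% relative once \eqn{D_{eff}\pi^2 t/a^2 > 1}.
#'
#' @inheritParams fick_series_mr
#' @return Approximate moisture ratio, same length as `t`.
#' @export
one_term_mr <- function(deff, geom = grain_geometry(), t) {
  g <- as_grain_geometry(geom)
  t <- check_time(t)
  stopifnot(is.numeric(deff), length(deff) == 1L, deff >= 0)
  (6 / pi^2) * exp(-deff * pi^2 * t / g$radius_a^2)
}

#' Effective diffusivity from the rate constant
#'
#' The one-term sphere solution identifies the drying rate constant with
#' the effective diffusivity through \eqn{D_{eff} = k a^2 / \pi^2}. The
#' result carries both the per-minute value (the package's working unit)
#' and the per-hour view conventionally reported for grain drying.
#'
#' @param k Rate constant, per minute, `> 0`.
#' @param geom A [grain_geometry()] object (or a bare radius in meters).
#' @return An object of class `diffusivity_result`: list with `deff`
#'   (m^2/min), `deff_per_h` (m^2/h), `k` (per min) and `radius_a` (m).
#' @seealso [k_from_deff()] for the inverse.
#' @export
deff_from_k <- function(k, geom = grain_geometry()) {
  g <- as_grain_geometry(geom)
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
  if (k <= 0) stop("`k` must be > 0 per minute; got ", k)
  deff <- k * g$radius_a^2 / pi^2
  structure(list(deff = deff, deff_per_h = 60 * deff,
                 k = k, radius_a = g$radius_a),
            class = "diffusivity_result")
}

#' @export
print.diffusivity_result <- function(x, ...) {
  cat(sprintf("<diffusivity_result> Deff = %.4g m^2/min (%.3g m^2/h), k = %.4g /min, a = %.4g m\n",
              x$deff, x$deff_per_h, x$k, x$radius_a))
  invisible(x)
}

#' Rate constant from the effective diffusivity
#'
#' Inverse of [deff_from_k()]: \eqn{k = \pi^2 D_{eff} / a^2}.
#'
#' @param deff Effective diffusivity, m\eqn{^2} per minute, `> 0`. A
#'   `diffusivity_result` is also accepted.
#' @inheritParams deff_from_k
#' @return Rate constant, per minute.
#' @export
k_from_deff <- function(deff, geom = grain_geometry()) {
  if (inherits(deff, "diffusivity_result")) {
    geom <- grain_geometry(deff$radius_a)
    deff <- deff$deff
  }
  g <- as_grain_geometry(geom)
  stopifnot(is.numeric(deff), length(deff) == 1L, is.finite(deff))
  if (deff <= 0) stop("`deff` must be > 0 m^2/min; got ", deff)
  pi^2 * deff / g$radius_a^2
}

#' Moisture curve parameterized by the effective diffusivity
#'
#' Identical to [moisture_at_time()] after substituting
#' \eqn{k = \pi^2 D_{eff}/a^2}:
#' \eqn{M(t) = (M_0 - M_E)\exp(-\pi^2 D_{eff} t / a^2) + M_E}.
#'
#' @param m0,me Initial and equilibrium moisture, percent.
#' @param deff Effective diffusivity, m\eqn{^2} per minute, `> 0`.
#' @inheritParams fick_series_mr
#' @return Moisture percent, same length as `t`.
#' @export
moisture_via_deff <- function(m0, me, deff, geom = grain_geometry(), t) {
  k <- k_from_deff(deff, geom)
  moisture_at_time(kinetic_params(m0 = m0, me = me, k = k), t)
}

#' Diffusivity rate
#'
#' The sensitivity of the moisture curve to the rate constant,
#' \deqn{v_k(t) = \frac{\partial M}{\partial k} = -t\,(M_0 - M_E)\,e^{-kt},}
#' in percent·minutes. It is zero at `t = 0`, its magnitude peaks at
#' exactly \eqn{t = 1/k} (see [vk_peak_time()]), and it decays to zero for
#' large `t`. Since \eqn{k \propto D_{eff}}, it equally measures how the
#' curve responds to a change in effective diffusivity.
#'
#' @inheritParams moisture_at_time
#' @return Percent·minutes (non-positive), same length as `t`.
#' @export
diffusivity_rate_vk <- function(params, t) {
  p <- as_kinetic_params(params)
  t <- check_time(t)
  -t * (p$m0 - p$me) * exp(-p$k * t)
}

#' Time at which the diffusivity-rate magnitude peaks
#'
#' \eqn{|v_k(t)| = t (M_0-M_E) e^{-kt}} has a unique interior maximum at
#' \eqn{t = 1/k} (set the derivative \eqn{(1 - kt)(M_0-M_E)e^{-kt}} to
#' zero).
#'
#' @inheritParams moisture_at_time
#' @return Time in minutes.
#' @export
vk_peak_time <- function(params) {
  p <- as_kinetic_params(params)
  1 / p$k
}
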