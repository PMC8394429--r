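#' Kinetic parameters of the first-order dehydration model
#'
#' Bundles the triple \eqn{(M_0, M_E, k)} that fully determines one
#' isothermal drying condition: the initial moisture \eqn{M_0}, the
#' equilibrium (asymptotic) moisture \eqn{M_E}, and the dynamical rate
#' constant \eqn{k}. The model is
#' \deqn{M(t) = (M_0 - M_E)\,e^{-kt} + M_E,}
#' the solution of \eqn{dM/dt = -k\,[M(t) - M_E]} under the border
#' conditions \eqn{M(0) = M_0} and \eqn{M(t) \to M_E} as \eqn{t \to \infty}.
#'
#' Moisture is a percentage on whatever basis (wet or dry) the data were
#' recorded; the model is basis-agnostic. Time is in minutes throughout, so
#' \eqn{k} is per minute.
#'
#' @param m0 Initial moisture, percent. Must satisfy `me < m0 <= 100`.
#' @param me Equilibrium moisture, percent, `>= 0`.
#' @param k Rate constant, per minute, `> 0`.
#'
#' @return An object of class `kinetic_params`: a named list with elements
#'   `m0`, `me`, `k`.
#' @examples
#' p <- kinetic_params(m0 = 47, me = 5.088, k = 0.0185)
#' moisture_at_time(p, c(0, 15, 60, 2600))
#' @export
kinetic_params <- function(m0, me, k) {
  stopifnot(is.numeric(m0), length(m0) == 1L, is.finite(m0),
            is.numeric(me), length(me) == 1L, is.finite(me),
            is.numeric(k),  length(k)  == 1L, is.finite(k))
  if (k <= 0) stop("`k` must be > 0 (per minute); got ", k)
  if (me < 0) stop("`me` must be >= 0 percent; got ", me)
  if (m0 <= me) stop("`m0` must exceed `me`; got m0 = ", m0, ", me = ", me)
  if (m0 > 100) stop("`m0` is a percentage and cannot exceed 100; got ", m0)
  structure(list(m0 = m0, me = me, k = k), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> M0 = %.4g%%, ME = %.4g%%, k = %.4g /min\n",
              x$m0, x$me, x$k))
  invisible(x)
}

as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  if (is.list(x) && all(c("m0", "me", "k") %in% names(x)))
    return(kinetic_params(x$m0, x$me, x$k))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as kinetic parameters")
}

check_time <- function(t) {
  if (!is.numeric(t) || anyNA(t))
    stop("`t` must be numeric and non-missing")
  if (any(t < 0))
    stop("`t` must be >= 0 minutes; got negative time ", min(t))
  t
}

#' Moisture at a given drying time
#'
#' Evaluates \eqn{M(t) = (M_0 - M_E)e^{-kt} + M_E}. Strictly decreasing in
#' `t`, from \eqn{M_0} at `t = 0` towards the asymptote \eqn{M_E}.
#'
#' @param params A [kinetic_params()] object.
#' @param t Drying time(s), minutes, `>= 0`. Vectorized.
#' @return Moisture percent, same length as `t`.
#' @seealso [time_for_moisture()] for the inverse, [moisture_asymptote()]
#'   for the \eqn{t \to \infty} limit.
#' @export
moisture_at_time <- function(params, t) {
  p <- as_kinetic_params(params)
  t <- check_time(t)
  (p$m0 - p$me) * exp(-p$k * t) + p$me
}

#' Isothermal dehydration rate
#'
#' The time derivative of the moisture curve,
#' \eqn{v_I(t) = dM/dt = -k (M_0 - M_E) e^{-kt} = -k\,[M(t) - M_E]}.
#' Always negative during drying (moisture is being lost); its magnitude
#' decreases monotonically towards 0.
#'
#' @inheritParams moisture_at_time
#' @return Rate, percent per minute (negative), same length as `t`.
#' @export
dehydration_rate <- function(params, t) {
  p <- as_kinetic_params(params)
  t <- check_time(t)
  -p$k * (p$m0 - p$me) * exp(-p$k * t)
}

#' Initial dehydration rate
#'
#' \eqn{v_0 = -k (M_0 - M_E)}, the drying rate at `t = 0`.
#'
#' @inheritParams moisture_at_time
#' @return A single negative number, percent per minute.
#' @export
initial_rate <- function(params) {
  p <- as_kinetic_params(params)
  -p$k * (p$m0 - p$me)
}

#' Moisture ratio
#'
#' The normalized moisture
#' \eqn{MR(t) = (M(t) - M_E)/(M_0 - M_E) = e^{-kt}}, decaying from 1 at
#' `t = 0` towards 0.
#'
#' @inheritParams moisture_at_time
#' @return Dimensionless value in `(0, 1]`, same length as `t`.
#' @export
moisture_ratio <- function(params, t) {
  p <- as_kinetic_params(params)
  t <- check_time(t)
  exp(-p$k * t)
}

#' Time to reach a target moisture
#'
#' Inverts the moisture curve:
#' \eqn{t = (1/k)\,\ln[(M_0 - M_E)/(m - M_E)]}.
#' Equilibrium is approached only asymptotically, so a target at or below
#' \eqn{M_E} is an error rather than `Inf`.
#'
#' @inheritParams moisture_at_time
#' @param m Target moisture percent(s), each in `(me, m0]`. Vectorized.
#' @return Time in minutes, same length as `m`.
#' @export
time_for_moisture <- function(params, m) {
  p <- as_kinetic_params(params)
  if (!is.numeric(m) || anyNA(m)) stop("`m` must be numeric and non-missing")
  if (any(m <= p$me))
    stop("target moisture ", min(m), "% is at or below the equilibrium ",
         "moisture ME = ", p$me, "%: unreachable in finite time")
  if (any(m > p$m0))
    stop("target moisture ", max(m), "% exceeds the initial moisture M0 = ",
         p$m0, "%")
  log((p$m0 - p$me) / (m - p$me)) / p$k
}

#' Asymptotic moisture limits
#'
#' The two border values of the model: `initial` is \eqn{M(0) = M_0} and
#' `equilibrium` is \eqn{\lim_{t\to\infty} M(t) = M_E}. The corresponding
#' rate limits are \eqn{v_0} at `t = 0` (see [initial_rate()]) and 0 at
#' infinity.
#'
#' @inheritParams moisture_at_time
#' @return Named numeric vector `c(initial = m0, equilibrium = me)`.
#' @export
moisture_asymptote <- function(params) {
  p <- as_kinetic_params(params)
  c(initial = p$m0, equilibrium = p$me)
}
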