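#' Moisture trajectory for one steeping-time condition
#'
#' A validated container for timestamped moisture observations from a single
#' steeping-time (ST) condition, optionally with replicate labels. Fitting
#' functions accept it directly.
#'
#' @param time_min Observation times, minutes, `>= 0`.
#' @param moisture_pct Moisture percentages in `[0, 100]`.
#' @param st_h Steeping time, hours (single value; `NA` if unknown).
#' @param replicate Optional replicate identifiers, same length as
#'   `time_min`.
#' @return A data frame of class `moisture_series` with columns `time_min`,
#'   `moisture_pct` and (if given) `replicate`; the steeping time is stored
#'   in attribute `st_h`.
#' @export
moisture_series <- function(time_min, moisture_pct, st_h = NA_real_,
                            replicate = NULL) {
  stopifnot(is.numeric(time_min), is.numeric(moisture_pct),
            length(time_min) == length(moisture_pct))
  if (anyNA(time_min) || anyNA(moisture_pct))
    stop("missing values in the trajectory")
  if (any(time_min < 0)) stop("observation times must be >= 0 minutes")
  if (any(moisture_pct < 0 | moisture_pct > 100))
    stop("moisture percentages must lie in [0, 100]")
  df <- data.frame(time_min = time_min, moisture_pct = moisture_pct)
  if (!is.null(replicate)) {
    stopifnot(length(replicate) == length(time_min))
    df$replicate <- replicate
  }
  structure(df, st_h = st_h, class = c("moisture_series", "data.frame"))
}

# replicate means per time point, sorted by time
aggregate_series <- function(series) {
  agg <- stats::aggregate(moisture_pct ~ time_min, data = series, FUN = mean)
  agg[order(agg$time_min), , drop = FALSE]
}

# deterministic multiplicative jitters for fit restarts (fixed seed)
restart_jitter <- function(n_restarts, n_par) {
  seed_keep <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(seed_keep)) assign(".Random.seed", seed_keep, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(20210730L)
  matrix(stats::runif(n_restarts * n_par, 0.7, 1.3), nrow = n_restarts)
}

#' Fit the three-parameter exponential drying model
#'
#' Recovers \eqn{(M_0, M_E, k)} from one trajectory by nonlinear least
#' squares on \eqn{M(t) = (M_0 - M_E) e^{-kt} + M_E}, using
#' Levenberg--Marquardt with box bounds. Replicates are averaged per time
#' point before fitting unless `use_replicates = TRUE`, in which case every
#' raw observation enters the sum of squares.
#'
#' Starting values are data-driven and deterministic: \eqn{M_0} from the
#' first observation, \eqn{M_E} from the last, and \eqn{k} from the
#' log-linear slope (falling back to 0.01/min if that slope is unusable).
#' Up to three restarts with deterministically jittered starts are tried
#' before non-convergence is reported.
#'
#' @param series A [moisture_series()] (or a data frame with columns
#'   `time_min`, `moisture_pct` and optionally `replicate`).
#' @param init Optional [kinetic_params()] overriding the automatic start.
#' @param use_replicates If `TRUE`, fit raw replicate observations instead
#'   of per-time means.
#' @return An object of class `fit_result`: list with `params`
#'   ([kinetic_params()]), `r_squared`, `residuals`, `fitted`, `n_obs`,
#'   `method = "nls"` and `st_h`.
#' @examples
#' p <- kinetic_params(47, 5.088, 0.0185)
#' tt <- c(seq(0, 120, by = 15), 2600)
#' s <- moisture_series(tt, moisture_at_time(p, tt), st_h = 0)
#' fit_exponential(s)
#' @export
fit_exponential <- function(series, init = NULL, use_replicates = FALSE) {
  dat <- if (use_replicates) {
    series[order(series$time_min), c("time_min", "moisture_pct")]
  } else {
    aggregate_series(series)
  }
  if (length(unique(dat$time_min)) < 4L)
    stop("need at least 4 distinct observation times for a 3-parameter fit; got ",
         length(unique(dat$time_min)))
  if (diff(range(dat$moisture_pct)) == 0)
    stop("trajectory is constant: the drying model is unidentifiable")

  m0_0 <- dat$moisture_pct[1L]
  me_0 <- dat$moisture_pct[nrow(dat)]
  k_0 <- tryCatch({
    ok <- dat$moisture_pct > me_0 & dat$time_min < max(dat$time_min)
    sl <- stats::coef(stats::lm(log(dat$moisture_pct[ok] - me_0) ~
                                  dat$time_min[ok]))[[2L]]
    if (is.finite(sl) && sl < 0) -sl else 0.01
  }, error = function(e) 0.01)
  if (!is.null(init)) {
    ip <- as_kinetic_params(init)
    m0_0 <- ip$m0; me_0 <- ip$me; k_0 <- ip$k
  }

  lower <- c(m0 = min(me_0, m0_0), me = 0, k = 1e-6)
  upper <- c(m0 = 100, me = max(m0_0, me_0), k = 1)
  starts <- rbind(c(m0_0, me_0, k_0),
                  c(m0_0, me_0, k_0) * restart_jitter(3L, 3L))
  colnames(starts) <- c("m0", "me", "k")

  fit <- NULL; last_err <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- pmin(pmax(starts[i, ], lower + 1e-9), upper - 1e-9)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        moisture_pct ~ (m0 - me) * exp(-k * time_min) + me,
        data = dat, start = as.list(st),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                             maxiter = 500)),
      error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("nonlinear fit failed to converge after restarts: ",
         conditionMessage(last_err))

  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  sstot <- sum((dat$moisture_pct - mean(dat$moisture_pct))^2)
  structure(list(
    params = kinetic_params(cf[["m0"]], cf[["me"]], cf[["k"]]),
    r_squared = 1 - sum(res^2) / sstot,
    residuals = as.numeric(res),
    fitted = as.numeric(stats::fitted(fit)),
    n_obs = nrow(dat),
    method = "nls",
    st_h = attr(series, "st_h", exact = TRUE) %||% NA_real_
  ), class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> method = %s, n = %d, R^2 = %.5f\n",
              x$method, x$n_obs, x$r_squared))
  print(x$params)
  invisible(x)
}

#' Log-linear (slope-method) estimate of the rate constant
#'
#' With a known equilibrium moisture, the model linearizes:
#' \eqn{\ln[M(t) - M_E] = \ln(M_0 - M_E) - kt}, so an ordinary
#' least-squares line through \eqn{(t, \ln[M(t) - M_E])} has slope
#' \eqn{-k}. The reported intercept is on the moisture-ratio scale,
#' \eqn{\ln[(M - M_E)/(\hat M_0 - M_E)]} with \eqn{\hat M_0} the first
#' observation, so it is 0 for noiseless model data.
#'
#' @inheritParams fit_exponential
#' @param me Equilibrium moisture, percent; every observation must exceed
#'   it (the log argument must be positive).
#' @return List with `k` (per minute), `intercept` (log moisture-ratio
#'   scale), `m0` (the anchor \eqn{\hat M_0}), `me`, and
#'   `method = "loglinear"`.
#' @export
fit_loglinear <- function(series, me) {
  dat <- aggregate_series(series)
  bad <- dat$moisture_pct <= me
  if (any(bad))
    stop("observation at t = ", dat$time_min[which(bad)[1L]],
         " min has moisture ", dat$moisture_pct[which(bad)[1L]],
         "% <= ME = ", me, "%: log-linearization undefined")
  y <- log(dat$moisture_pct - me)
  co <- stats::coef(stats::lm(y ~ dat$time_min))
  m0_hat <- dat$moisture_pct[1L]
  list(k = -co[[2L]],
       intercept = co[[1L]] - log(m0_hat - me),
       m0 = m0_hat, me = me, method = "loglinear")
}

#' Fit every steeping-time condition in a dataset
#'
#' Splits a trajectory dataset by steeping time, fits the exponential model
#' to each condition with [fit_exponential()], and assembles the results in
#' one table (one row per ST), mirroring how a per-ST rate-equation table
#' is reported.
#'
#' @param data Data frame in the canonical trajectory schema: columns
#'   `steeping_time_h`, `time_min`, `replicate`, `moisture_pct` (see
#'   [read_trajectories()]).
#' @inheritParams fit_exponential
#' @return A data frame of class `fit_table` with columns `st_h`, `m0`,
#'   `me`, `k`, `v0`, `r_squared`, `n_obs`, `method`, sorted by `st_h`.
#'   The full `fit_result` objects are kept in attribute `fits`.
#' @export
fit_all_st <- function(data, use_replicates = FALSE) {
  data <- validate_trajectories(data)
  if (nrow(data) == 0L) stop("empty dataset: nothing to fit")
  sts <- sort(unique(data$steeping_time_h))
  fits <- lapply(sts, function(st) {
    sub <- data[data$steeping_time_h == st, , drop = FALSE]
    tryCatch(
      fit_exponential(moisture_series(sub$time_min, sub$moisture_pct,
                                      st_h = st, replicate = sub$replicate),
                      use_replicates = use_replicates),
      error = function(e)
        stop("fit failed for ST = ", st, " h: ", conditionMessage(e),
             call. = FALSE))
  })
  names(fits) <- as.character(sts)
  tab <- data.frame(
    st_h = sts,
    m0 = vapply(fits, function(f) f$params$m0, numeric(1)),
    me = vapply(fits, function(f) f$params$me, numeric(1)),
    k = vapply(fits, function(f) f$params$k, numeric(1)),
    v0 = vapply(fits, function(f) initial_rate(f$params), numeric(1)),
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
    n_obs = vapply(fits, function(f) f$n_obs, integer(1)),
    method = vapply(fits, function(f) f$method, character(1)),
    row.names = NULL
  )
  structure(tab, fits = fits, class = c("fit_table", "data.frame"))
}

#' Initial dehydration rate per steeping time
#'
#' Tabulates \eqn{v_0 = -k (M_0 - M_E)} for every fitted condition — the
#' quantity whose dependence on steeping time (and on \eqn{M_0}) summarizes
#' how steeping changes the grain's surface drying behaviour.
#'
#' @param fits A `fit_table` from [fit_all_st()].
#' @return Data frame with columns `st_h`, `v0` (percent/min, negative) and
#'   `m0` (percent).
#' @export
v0_series <- function(fits) {
  stopifnot(is.data.frame(fits), all(c("st_h", "m0", "me", "k") %in% names(fits)))
  data.frame(
    st_h = fits$st_h,
    v0 = mapply(function(m0, me, k) initial_rate(kinetic_params(m0, me, k)),
                fits$m0, fits$me, fits$k),
    m0 = fits$m0
  )
}
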