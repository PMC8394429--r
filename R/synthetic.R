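#' Experimental design of a steeping-time dehydration study
#'
#' Describes the measurement layout the generator emulates: grains
#' nixtamalized and steeped for each steeping time, then dried at constant
#' temperature with weighings every 15 min over the first two hours and one
#' long-time weighing (2600 min) to pin down the equilibrium moisture, with
#' five independent replicates per steeping time.
#'
#' @param st_values_h Steeping times, hours.
#' @param sample_times_min Weighing times, minutes; sorted, unique, `>= 0`.
#' @param replicates Replicates per steeping time, `>= 1`.
#' @param seed Integer seed making generation reproducible.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(st_values_h = c(0, 2, 4, 6, 8),
                              sample_times_min = c(seq(0, 120, by = 15), 2600),
                              replicates = 5L,
                              seed = 1L) {
  stopifnot(is.numeric(st_values_h), length(st_values_h) >= 1L,
            is.numeric(sample_times_min), length(sample_times_min) >= 1L)
  if (replicates < 1L) stop("`replicates` must be >= 1")
  if (any(sample_times_min < 0)) stop("sample times must be >= 0 minutes")
  if (anyDuplicated(sample_times_min)) stop("sample times must be unique")
  structure(list(st_values_h = sort(st_values_h),
                 sample_times_min = sort(sample_times_min),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' Time-dependent measurement-noise model
#'
#' Moisture weighings are noisiest early in drying and stabilize at long
#' times. The generator draws Gaussian noise whose standard deviation
#' interpolates from `sd_at_t0` at `t = 0` down to `sd_at_tmax` at the last
#' sample time, linearly in `log(1 + t)`. The defaults span the
#' 0.181--0.993 percentage-point uncertainty band of the emulated
#' experiment.
#'
#' @param sd_at_t0 Noise sd at `t = 0`, percentage points, `>= 0`.
#' @param sd_at_tmax Noise sd at the last sample time, `>= 0`, not larger
#'   than `sd_at_t0`. Set both to 0 for noiseless generation.
#' @param schedule Interpolation schedule tag (only `"linear-in-log-time"`).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd_at_t0 = 0.993, sd_at_tmax = 0.181,
                        schedule = "linear-in-log-time") {
  stopifnot(is.numeric(sd_at_t0), is.numeric(sd_at_tmax))
  if (sd_at_t0 < 0 || sd_at_tmax < 0) stop("noise sds must be >= 0")
  if (sd_at_tmax > sd_at_t0)
    stop("noise sd must be non-increasing in time: sd_at_tmax > sd_at_t0")
  schedule <- match.arg(schedule)
  structure(list(sd_at_t0 = sd_at_t0, sd_at_tmax = sd_at_tmax,
                 schedule = schedule),
            class = "noise_model")
}

#' Noise standard deviation at given times
#'
#' Evaluates the [noise_model()] schedule:
#' `sd(t) = sd0 + (sd1 - sd0) * log(1 + t) / log(1 + t_max)`.
#'
#' @param noise A [noise_model()].
#' @param t Times, minutes.
#' @param t_max Time at which the sd reaches `sd_at_tmax`, minutes.
#' @return Standard deviations, percentage points.
#' @export
noise_sd <- function(noise, t, t_max = 2600) {
  stopifnot(inherits(noise, "noise_model"))
  t <- check_time(t)
  if (t_max <= 0) return(rep(noise$sd_at_t0, length(t)))
  noise$sd_at_t0 +
    (noise$sd_at_tmax - noise$sd_at_t0) * log1p(t) / log1p(t_max)
}

# reference (ME, k) per steeping time; M0 is a synthetic profile (no
# measured M0 values exist to anchor it) consistent with M0 rising with ST
# towards a ~47% ceiling
.default_param_rows <- data.frame(
  st_h = c(0, 2, 4, 6, 8),
  m0 = c(38, 45, 47, 46.5, 46),
  me = c(5.088, 5.399, 5.792, 5.646, 5.836),
  k = c(0.0185, 0.0161, 0.0158, 0.0147, 0.0140)
)

#' Reference kinetic parameters for a steeping time
#'
#' Returns the generating parameters used by the synthetic module for one
#' of the five design steeping times. The equilibrium moistures and rate
#' constants are the fitted per-ST values of the emulated study; the
#' initial moistures are a synthetic profile (no measured values exist),
#' increasing with steeping time towards a ceiling of about 47\%.
#'
#' @param st_h Steeping time, hours; must be one of 0, 2, 4, 6, 8.
#' @return A [kinetic_params()] object.
#' @seealso [default_params_table()] for all five rows at once.
#' @export
default_params_for_st <- function(st_h) {
  i <- match(st_h, .default_param_rows$st_h)
  if (is.na(i))
    stop("no reference parameters for ST = ", st_h,
         " h; available: ", paste(.default_param_rows$st_h, collapse = ", "))
  with(.default_param_rows[i, ], kinetic_params(m0, me, k))
}

#' Reference parameter table for all design steeping times
#'
#' @return Data frame with columns `st_h`, `m0`, `me`, `k` and
#'   `m0_synthetic` (all `TRUE`: the `m0` column is a modelled stand-in,
#'   not a measured quantity).
#' @export
default_params_table <- function() {
  out <- .default_param_rows
  out$m0_synthetic <- TRUE
  out
}

# run expr with a private, seeded RNG stream; global RNG state untouched
with_seed <- function(seed, expr) {
  seed_keep <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(seed_keep)) assign(".Random.seed", seed_keep, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate synthetic dehydration trajectories
#'
#' Simulates the full measurement campaign: for every (steeping time,
#' weighing time, replicate) cell, the model moisture plus Gaussian noise
#' with the time-dependent sd of the [noise_model()], clipped below at 0
#' (a clipped value is flagged). Generation is fully reproducible from the
#' design seed and leaves the caller's RNG state untouched.
#'
#' @param design An [experiment_design()].
#' @param params_table Data frame with columns `st_h`, `m0`, `me`, `k`
#'   covering every design steeping time; defaults to
#'   [default_params_table()].
#' @param noise A [noise_model()]; use `noise_model(0, 0)` for noiseless
#'   trajectories.
#' @return Data frame in the canonical trajectory schema
#'   (`steeping_time_h`, `time_min`, `replicate`, `moisture_pct`) plus a
#'   logical `clipped` column, with the generating parameters attached as
#'   attribute `params_table` and the design as attribute `design`.
#' @examples
#' d <- generate_trajectories(experiment_design(seed = 42))
#' nrow(d)  # 5 STs x 10 times x 5 replicates = 250
#' @export
generate_trajectories <- function(design = experiment_design(),
                                  params_table = default_params_table(),
                                  noise = noise_model()) {
  stopifnot(inherits(design, "experiment_design"),
            is.data.frame(params_table),
            all(c("st_h", "m0", "me", "k") %in% names(params_table)))
  miss <- setdiff(design$st_values_h, params_table$st_h)
  if (length(miss))
    stop("params_table lacks rows for ST = ", paste(miss, collapse = ", "))

  grid <- expand.grid(replicate = seq_len(design$replicates),
                      time_min = design$sample_times_min,
                      steeping_time_h = design$st_values_h,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("steeping_time_h", "time_min", "replicate")]
  grid <- grid[order(grid$steeping_time_h, grid$time_min, grid$replicate), ]
  rownames(grid) <- NULL

  i <- match(grid$steeping_time_h, params_table$st_h)
  mu <- (params_table$m0[i] - params_table$me[i]) *
    exp(-params_table$k[i] * grid$time_min) + params_table$me[i]
  sd_t <- noise_sd(noise, grid$time_min,
                   t_max = max(design$sample_times_min))
  raw <- with_seed(design$seed, mu + stats::rnorm(nrow(grid), 0, sd_t))
  grid$moisture_pct <- pmax(raw, 0)
  grid$clipped <- raw < 0
  structure(grid, params_table = params_table, design = design)
}
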