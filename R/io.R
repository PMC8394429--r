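#' @keywords internal
"_PACKAGE"

TRAJ_COLS <- c("steeping_time_h", "time_min", "replicate", "moisture_pct")

# schema checks shared by read_trajectories and fit_all_st
validate_trajectories <- function(data) {
  stopifnot(is.data.frame(data))
  miss <- setdiff(TRAJ_COLS, names(data))
  if (length(miss))
    stop("trajectory data lacks column(s): ", paste(miss, collapse = ", "))
  for (cl in setdiff(TRAJ_COLS, "replicate"))
    if (!is.numeric(data[[cl]]))
      stop("column `", cl, "` must be numeric")
  if (nrow(data)) {
    if (any(data$time_min < 0)) stop("`time_min` must be >= 0")
    if (any(data$moisture_pct < 0 | data$moisture_pct > 100))
      stop("`moisture_pct` must lie in [0, 100]")
    key <- paste(data$steeping_time_h, data$time_min, data$replicate)
    if (anyDuplicated(key))
      stop("duplicate (steeping_time_h, time_min, replicate) key(s): ",
           key[anyDuplicated(key)])
  }
  data[TRAJ_COLS]
}

#' Read dehydration trajectories from CSV
#'
#' Reads the canonical trajectory schema — a CSV with header
#' `steeping_time_h,time_min,replicate,moisture_pct` — and validates it:
#' all cells numeric, times non-negative, moistures in `[0, 100]`, no
#' duplicate (ST, time, replicate) key. Malformed rows are reported with
#' their file line numbers. A header-only file yields an empty dataset
#' with a warning.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame with the four schema columns.
#' @seealso [write_trajectories()]
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE)
  miss <- setdiff(TRAJ_COLS, names(raw))
  if (length(miss))
    stop("`", path, "` lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("`", path, "` contains a header but no data rows")
    return(validate_trajectories(
      data.frame(steeping_time_h = numeric(), time_min = numeric(),
                 replicate = numeric(), moisture_pct = numeric())))
  }
  out <- raw[TRAJ_COLS]
  for (cl in TRAJ_COLS) {
    v <- suppressWarnings(as.numeric(out[[cl]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("`", path, "`: non-numeric value \"", out[[cl]][bad[1L]],
           "\" in column `", cl, "` at file line ", bad[1L] + 1L,
           " (header is line 1)")
    out[[cl]] <- v
  }
  validate_trajectories(out)
}

#' Write dehydration trajectories to CSV
#'
#' Writes the canonical trajectory schema with 10 significant digits, so a
#' write--read round trip reproduces the values exactly at that precision
#' and identical inputs produce byte-identical files.
#'
#' @param data Trajectory data frame (extra columns such as `clipped` are
#'   preserved).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(data, path) {
  validate_trajectories(data)
  out <- data
  for (cl in names(out))
    if (is.numeric(out[[cl]])) out[[cl]] <- format(out[[cl]], digits = 10,
                                                   trim = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an isoline grid as a CSV matrix
#'
#' First column is the steeping-time axis (`st_h`); remaining columns are
#' the grid values, one per drying-time node, named `t_<minutes>`.
#'
#' @param grid An `isoline_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "isoline_grid"))
  df <- data.frame(st_h = grid$st_axis)
  vals <- as.data.frame(signif(grid$values, 10))
  names(vals) <- paste0("t_", grid$t_axis)
  utils::write.csv(cbind(df, vals), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every knob of [run_pipeline()] in one validated object.
#'
#' @param input Path to a trajectory CSV, or `NULL` to simulate with the
#'   synthetic generator.
#' @param output_dir Directory for reports and grids; created if needed.
#'   `NULL` writes nothing and only returns the report.
#' @param seed Integer seed for simulation.
#' @param design An [experiment_design()] (its own seed is overridden by
#'   `seed`).
#' @param noise A [noise_model()].
#' @param params_table Generating-parameter table for simulation.
#' @param st_step,t_step Grid resolution: steeping-time step (hours) and
#'   drying-time step (minutes).
#' @param t_max Last drying time on the grid, minutes.
#' @param n_levels Number of isoline levels per grid.
#' @param interpolation Surface interpolation tag (see
#'   [build_param_surface()]).
#' @param use_replicates Fit raw replicates instead of per-time means.
#' @param verbose Log each stage to the console.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, output_dir = NULL, seed = 1L,
                       design = experiment_design(),
                       noise = noise_model(),
                       params_table = default_params_table(),
                       st_step = 0.1, t_step = 10, t_max = 2600,
                       n_levels = 14L,
                       interpolation = c("linear", "monotone-cubic"),
                       use_replicates = FALSE, verbose = FALSE) {
  stopifnot(st_step > 0, t_step > 0, t_max > 0, n_levels >= 1L)
  design$seed <- as.integer(seed)
  structure(list(input = input, output_dir = output_dir,
                 seed = as.integer(seed), design = design, noise = noise,
                 params_table = params_table, st_step = st_step,
                 t_step = t_step, t_max = t_max,
                 n_levels = as.integer(n_levels),
                 interpolation = match.arg(interpolation),
                 use_replicates = isTRUE(use_replicates),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the full dehydration-analysis pipeline
#'
#' Executes simulate (or load) → per-ST fitting → effective diffusivities →
#' initial rates → moisture and rate surfaces with isolines, and writes a
#' JSON report plus CSV grid/isoline exports when an output directory is
#' configured. The run is deterministic for a fixed configuration and
#' seed.
#'
#' @param config A [run_config()].
#' @return The report, invisibly: a list with elements `fits`, `deff`,
#'   `v0`, `isolines` (level counts) and `meta`.
#' @examples
#' rep <- run_pipeline(run_config(seed = 7))
#' rep$fits
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message("[nixdry] ", ...)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }

  traj <- stage("input", {
    if (is.null(config$input)) {
      say("simulating trajectories (seed ", config$seed, ")")
      generate_trajectories(config$design, config$params_table,
                            config$noise)
    } else {
      say("reading trajectories from ", config$input)
      read_trajectories(config$input)
    }
  })

  say("fitting ", length(unique(traj$steeping_time_h)), " ST condition(s)")
  fits <- stage("fit", fit_all_st(traj,
                                  use_replicates = config$use_replicates))

  deff_tab <- stage("diffusivity", data.frame(
    st_h = fits$st_h,
    k = fits$k,
    deff_m2_min = vapply(fits$k, function(k) deff_from_k(k)$deff, numeric(1)),
    deff_m2_h = vapply(fits$k, function(k) deff_from_k(k)$deff_per_h,
                       numeric(1))
  ))
  v0_tab <- stage("rates", v0_series(fits))

  say("building surfaces (", config$st_step, " h x ", config$t_step,
      " min grid)")
  iso <- stage("isolines", {
    surface <- build_param_surface(fits, config$interpolation)
    st_axis <- seq(min(surface$st_nodes), max(surface$st_nodes),
                   by = config$st_step)
    t_axis <- seq(0, config$t_max, by = config$t_step)
    mg <- moisture_grid(surface, st_axis, t_axis, config$n_levels)
    rg <- rate_grid(surface, st_axis, t_axis, config$n_levels)
    list(surface = surface, moisture = mg, rate = rg,
         moisture_iso = extract_isoline(mg), rate_iso = extract_isoline(rg))
  })

  report <- list(
    fits = as.data.frame(fits),
    deff = deff_tab,
    v0 = v0_tab,
    isolines = list(moisture_levels = length(unique(iso$moisture_iso$level)),
                    rate_levels = length(unique(iso$rate_iso$level))),
    meta = list(seed = config$seed,
                version = as.character(utils::packageVersion("nixdry")),
                input = config$input %||% "synthetic",
                interpolation = config$interpolation,
                n_levels = config$n_levels)
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$output_dir, f)
    say("writing outputs to ", config$output_dir)
    jsonlite::write_json(report, p("report.json"), digits = I(10),
                         auto_unbox = TRUE, dataframe = "rows")
    write_grid_csv(iso$moisture, p("moisture_grid.csv"))
    write_grid_csv(iso$rate, p("rate_grid.csv"))
    utils::write.csv(iso$moisture_iso, p("moisture_isolines.csv"),
                     row.names = FALSE)
    utils::write.csv(iso$rate_iso, p("rate_isolines.csv"), row.names = FALSE)
    if (is.null(config$input))
      write_trajectories(traj, p("trajectories.csv"))
  }
  invisible(report)
}
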