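#' Parameter surface over steeping time
#'
#' Interpolates the fitted per-ST kinetic parameters component-wise in
#' steeping time, so the drying model can be evaluated at steeping times
#' between the measured conditions. Interpolation is exact at the nodes;
#' extrapolation beyond the node range is refused (there is no basis for
#' it).
#'
#' @param fits A `fit_table` from [fit_all_st()], or any data frame with
#'   columns `st_h`, `m0`, `me`, `k` (one row per ST).
#' @param interpolation `"linear"` (piecewise linear, the default: values
#'   stay within the convex hull of the node values) or `"monotone-cubic"`
#'   (Fritsch--Carlson monotone Hermite spline).
#' @return An object of class `param_surface`; evaluate it with
#'   [surface_params()].
#' @export
build_param_surface <- function(fits,
                                interpolation = c("linear", "monotone-cubic")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is.data.frame(fits),
            all(c("st_h", "m0", "me", "k") %in% names(fits)))
  if (nrow(fits) < 2L)
    stop("need at least 2 steeping-time nodes to build a surface; got ",
         nrow(fits))
  if (anyDuplicated(fits$st_h))
    stop("duplicate steeping-time nodes: ",
         paste(fits$st_h[duplicated(fits$st_h)], collapse = ", "))
  ord <- order(fits$st_h)
  nodes <- fits$st_h[ord]
  mk_fun <- function(y) {
    if (interpolation == "linear")
      stats::approxfun(nodes, y[ord], rule = 1)
    else
      stats::splinefun(nodes, y[ord], method = "monoH.FC")
  }
  structure(list(st_nodes = nodes,
                 m0 = mk_fun(fits$m0), me = mk_fun(fits$me),
                 k = mk_fun(fits$k),
                 node_table = data.frame(st_h = nodes, m0 = fits$m0[ord],
                                         me = fits$me[ord], k = fits$k[ord]),
                 interpolation = interpolation),
            class = "param_surface")
}

#' Kinetic parameters at an interpolated steeping time
#'
#' @param surface A [build_param_surface()] object.
#' @param st Steeping time, hours, within the node range.
#' @return A [kinetic_params()] object.
#' @export
surface_params <- function(surface, st) {
  stopifnot(inherits(surface, "param_surface"), length(st) == 1L)
  rng <- range(surface$st_nodes)
  if (st < rng[1L] || st > rng[2L])
    stop("ST = ", st, " h is outside the fitted node range [",
         rng[1L], ", ", rng[2L], "] h; extrapolation is not supported")
  kinetic_params(m0 = surface$m0(st), me = surface$me(st),
                 k = surface$k(st))
}

new_isoline_grid <- function(st_axis, t_axis, values, quantity,
                             n_levels = 14L) {
  structure(list(st_axis = st_axis, t_axis = t_axis, values = values,
                 quantity = quantity, n_levels = as.integer(n_levels)),
            class = "isoline_grid")
}

#' @export
print.isoline_grid <- function(x, ...) {
  cat(sprintf("<isoline_grid> %s, %d ST x %d time nodes, range [%.4g, %.4g]\n",
              x$quantity, length(x$st_axis), length(x$t_axis),
              min(x$values), max(x$values)))
  invisible(x)
}

check_grid_axes <- function(surface, st_axis, t_axis) {
  rng <- range(surface$st_nodes)
  if (any(st_axis < rng[1L]) || any(st_axis > rng[2L]))
    stop("`st_axis` extends beyond the fitted node range [",
         rng[1L], ", ", rng[2L], "] h; extrapolation is not supported")
  check_time(t_axis)
  stopifnot(!is.unsorted(st_axis, strictly = TRUE),
            !is.unsorted(t_axis, strictly = TRUE))
}

#' Moisture surface over the (steeping time, drying time) plane
#'
#' Evaluates the interpolated drying model on a rectangular grid:
#' `values[i, j] = M(t_j)` under the parameters at `st_axis[i]`. Isolines
#' of this surface answer "which (ST, drying time) combinations yield a
#' product at X\% moisture". The default grid covers the node range at
#' 0.1 h steps and 0--2600 min at 10 min steps.
#'
#' @param surface A [build_param_surface()] object.
#' @param st_axis Steeping times, hours, strictly increasing, within the
#'   node range.
#' @param t_axis Drying times, minutes, strictly increasing, `>= 0`.
#' @param n_levels Default number of contour levels carried by the grid.
#' @return An `isoline_grid` (quantity `"moisture"`), values in percent.
#' @export
moisture_grid <- function(surface,
                          st_axis = seq(min(surface$st_nodes),
                                        max(surface$st_nodes), by = 0.1),
                          t_axis = seq(0, 2600, by = 10),
                          n_levels = 14L) {
  check_grid_axes(surface, st_axis, t_axis)
  vals <- t(vapply(st_axis, function(st)
    moisture_at_time(surface_params(surface, st), t_axis),
    numeric(length(t_axis))))
  new_isoline_grid(st_axis, t_axis, vals, "moisture", n_levels)
}

#' Dehydration-rate surface over the (steeping time, drying time) plane
#'
#' As [moisture_grid()], but with `values[i, j] = v_I(t_j)`, the drying
#' rate in percent per minute. All entries are negative: the sign encodes
#' moisture loss.
#'
#' @inheritParams moisture_grid
#' @return An `isoline_grid` (quantity `"rate"`), values in percent/min.
#' @export
rate_grid <- function(surface,
                      st_axis = seq(min(surface$st_nodes),
                                    max(surface$st_nodes), by = 0.1),
                      t_axis = seq(0, 2600, by = 10),
                      n_levels = 14L) {
  check_grid_axes(surface, st_axis, t_axis)
  vals <- t(vapply(st_axis, function(st)
    dehydration_rate(surface_params(surface, st), t_axis),
    numeric(length(t_axis))))
  new_isoline_grid(st_axis, t_axis, vals, "rate", n_levels)
}

#' Default contour levels of a grid
#'
#' `n_levels` equally spaced interior levels of the grid's value range
#' (range endpoints excluded, as level sets there are degenerate).
#'
#' @param grid An `isoline_grid`.
#' @param n_levels Number of levels; defaults to the grid's own setting.
#' @return Numeric vector of levels.
#' @export
grid_levels <- function(grid, n_levels = grid$n_levels) {
  rng <- range(grid$values)
  seq(rng[1L], rng[2L], length.out = n_levels + 2L)[-c(1L, n_levels + 2L)]
}

#' Extract constant-value isolines from a grid
#'
#' Traces the level set `values == level` as polylines in (ST, drying
#' time) space by linear interpolation along grid-cell edges (the standard
#' marching-squares construction, via [grDevices::contourLines()]). A
#' level outside the grid's value range yields an empty result with a
#' warning; a constant grid is degenerate (the level set would be the
#' whole domain) and is likewise flagged.
#'
#' @param grid An `isoline_grid` from [moisture_grid()] or [rate_grid()].
#' @param level Contour level(s), in the grid's value units; defaults to
#'   [grid_levels()].
#' @return Data frame with columns `level`, `segment_id`, `st_h`,
#'   `time_min`; one row per polyline vertex.
#' @export
extract_isoline <- function(grid, level = grid_levels(grid)) {
  stopifnot(inherits(grid, "isoline_grid"))
  rng <- range(grid$values)
  empty <- data.frame(level = numeric(), segment_id = integer(),
                      st_h = numeric(), time_min = numeric())
  if (rng[1L] == rng[2L]) {
    warning("grid is constant at ", rng[1L],
            ": every requested level set is degenerate or empty")
    return(empty)
  }
  inside <- level > rng[1L] & level < rng[2L]
  if (!all(inside)) {
    warning("level(s) ", paste(level[!inside], collapse = ", "),
            " outside the open grid value range (", rng[1L], ", ", rng[2L],
            "): skipped")
    level <- level[inside]
    if (!length(level)) return(empty)
  }
  cl <- grDevices::contourLines(x = grid$st_axis, y = grid$t_axis,
                                z = grid$values, levels = level)
  if (!length(cl)) return(empty)
  out <- do.call(rbind, lapply(seq_along(cl), function(i)
    data.frame(level = cl[[i]]$level, segment_id = i,
               st_h = cl[[i]]$x, time_min = cl[[i]]$y)))
  rownames(out) <- NULL
  out
}

#' Drying time needed to reach a target moisture at a given steeping time
#'
#' Evaluates the inverse-time formula at the interpolated parameters for
#' `st`: the time at which the grain, steeped for `st` hours, reaches
#' `target_m` percent moisture during isothermal drying.
#'
#' @param surface A [build_param_surface()] object.
#' @param st Steeping time, hours, within the node range.
#' @param target_m Target moisture, percent, in `(me(st), m0(st)]`.
#' @return Drying time, minutes.
#' @export
time_to_target_moisture <- function(surface, st, target_m) {
  time_for_moisture(surface_params(surface, st), target_m)
}
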