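surface_from_refs <- function(interpolation = "linear") {
  build_param_surface(ref_table, interpolation)
}

test_that("parameter surface is exact at nodes and linear between them", {
  s <- surface_from_refs()
  for (st in ref_table$st_h) {
    p <- surface_params(s, st)
    r <- ref_table[ref_table$st_h == st, ]
    expect_equal(p$k, r$k); expect_equal(p$me, r$me); expect_equal(p$m0, r$m0)
  }
  # midway between the 2 h and 4 h nodes: arithmetic means
  p3 <- surface_params(s, 3)
  expect_equal(p3$k, (0.0161 + 0.0158) / 2, tolerance = 1e-12)
  expect_equal(p3$me, (5.399 + 5.792) / 2, tolerance = 1e-12)
  expect_equal(p3$m0, (45 + 47) / 2, tolerance = 1e-12)
  # monotone-cubic interpolant is also exact at nodes
  sc <- surface_from_refs("monotone-cubic")
  expect_equal(surface_params(sc, 4)$k, 0.0158, tolerance = 1e-12)
})

test_that("surface construction rejects degenerate node sets and extrapolation", {
  expect_error(build_param_surface(ref_table[1, ]), "at least 2")
  expect_error(build_param_surface(rbind(ref_table, ref_table[1, ])),
               "duplicate")
  s <- surface_from_refs()
  expect_error(surface_params(s, 8.5), "extrapolation")
  expect_error(surface_params(s, -1), "extrapolation")
  expect_error(moisture_grid(s, st_axis = seq(0, 9, 1)), "extrapolation")
})

test_that("grid rows at node STs equal the single-condition model curves", {
  s <- surface_from_refs()
  t_axis <- seq(0, 2600, by = 50)
  mg <- moisture_grid(s, st_axis = c(0, 2, 4, 6, 8), t_axis = t_axis)
  rg <- rate_grid(s, st_axis = c(0, 2, 4, 6, 8), t_axis = t_axis)
  for (i in seq_along(ref_table$st_h)) {
    p <- ref_params(ref_table$st_h[i])
    expect_equal(mg$values[i, ], moisture_at_time(p, t_axis),
                 tolerance = 1e-14)
    expect_equal(rg$values[i, ], dehydration_rate(p, t_axis),
                 tolerance = 1e-14)
  }
  # t = 0 columns are the M0 and v0 profiles
  expect_equal(mg$values[, 1], ref_table$m0)
  expect_equal(rg$values[, 1], -ref_table$k * (ref_table$m0 - ref_table$me))
})

test_that("moisture rows decrease in time; rate grid is negative with shrinking magnitude", {
  s <- surface_from_refs()
  mg <- moisture_grid(s, st_axis = seq(0, 8, 0.5), t_axis = seq(0, 600, 20))
  rg <- rate_grid(s, st_axis = seq(0, 8, 0.5), t_axis = seq(0, 600, 20))
  expect_true(all(apply(mg$values, 1, function(r) all(diff(r) < 0))))
  expect_true(all(rg$values < 0))
  expect_true(all(apply(abs(rg$values), 1, function(r) all(diff(r) < 0))))
  # cell-wise identity: v = -k(ST) (M - me(ST))
  k_st <- vapply(mg$st_axis, function(st) surface_params(s, st)$k, numeric(1))
  me_st <- vapply(mg$st_axis, function(st) surface_params(s, st)$me, numeric(1))
  expect_equal(rg$values, -k_st * (mg$values - me_st), tolerance = 1e-12)
})

test_that("extracted moisture isolines reproduce closed-form crossing times", {
  s <- surface_from_refs()
  t_axis <- seq(0, 300, by = 1)
  mg <- moisture_grid(s, st_axis = c(0, 2), t_axis = t_axis)
  iso <- extract_isoline(mg, level = 25)
  expect_true(nrow(iso) > 0)
  # at each node ST, the polyline's crossing time matches the inverse formula
  for (st in c(0, 2)) {
    pts <- iso[abs(iso$st_h - st) < 1e-9, ]
    expect_true(nrow(pts) >= 1)
    t_exact <- time_for_moisture(ref_params(st), 25)
    expect_lt(min(abs(pts$time_min - t_exact)), 1.0)  # within one t-cell
  }
})

test_that("out-of-range and degenerate isoline levels warn and return nothing", {
  s <- surface_from_refs()
  mg <- moisture_grid(s, st_axis = c(0, 4, 8), t_axis = seq(0, 600, 10))
  expect_warning(iso <- extract_isoline(mg, level = 2), "outside")
  expect_identical(nrow(iso), 0L)  # below every equilibrium moisture
  const <- structure(list(st_axis = c(0, 1), t_axis = c(0, 1),
                          values = matrix(5, 2, 2), quantity = "moisture",
                          n_levels = 3L),
                     class = "isoline_grid")
  expect_warning(iso2 <- extract_isoline(const, level = 5), "degenerate")
  expect_identical(nrow(iso2), 0L)
  # default levels span the interior of the value range
  lv <- grid_levels(mg)
  expect_length(lv, 14L)
  expect_true(all(lv > min(mg$values) & lv < max(mg$values)))
})

test_that("time-to-target queries work across the surface, including the 15-19% band", {
  s <- surface_from_refs()
  expect_equal(time_to_target_moisture(s, 4, 47), 0)
  # round trip against the grid crossing at an interpolated ST
  t_hit <- time_to_target_moisture(s, 3, 25)
  expect_equal(moisture_at_time(surface_params(s, 3), t_hit), 25,
               tolerance = 1e-10)
  for (st in ref_table$st_h) {
    for (m in c(15, 19)) {
      t_m <- time_to_target_moisture(s, st, m)
      expect_true(is.finite(t_m) && t_m > 0)
    }
  }
  expect_error(time_to_target_moisture(s, 2, 5.0), "unreachable")
})
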