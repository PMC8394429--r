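# brute-force partial sum of the Crank sphere series, independent of the
# package's truncation/early-exit logic
brute_sphere_mr <- function(deff, a, t, n_max = 10000L) {
  n <- seq_len(n_max)
  (6 / pi^2) * sum(exp(-deff * n^2 * pi^2 * t / a^2) / n^2)
}

test_that("sphere series is normalized to 1 at t = 0 and for zero diffusivity", {
  g <- grain_geometry()
  expect_equal(fick_series_mr(1e-7, g, 0, n_terms = 200), 1, tolerance = 1e-4)
  expect_equal(fick_series_mr(0, g, c(0, 50, 500)), rep(1, 3))
})

test_that("truncated series agrees with a 10,000-term brute-force sum", {
  a <- 0.0049
  deff <- 2.306e-6 / 60  # m^2/h expressed per minute
  for (t in c(1, 15, 60, 120)) {
    expect_equal(fick_series_mr(deff, grain_geometry(a), t, n_terms = 200),
                 brute_sphere_mr(deff, a, t), tolerance = 1e-10)
  }
})

test_that("sphere series decreases in time and in diffusivity", {
  g <- grain_geometry()
  tt <- seq(1, 2600, length.out = 40)
  mr <- fick_series_mr(3e-8, g, tt)
  expect_true(all(diff(mr) < 0))
  expect_true(all(mr >= 0 & mr <= 1))
  ds <- seq(1e-8, 1e-7, length.out = 20)
  at_t <- vapply(ds, function(d) fick_series_mr(d, g, 60), numeric(1))
  expect_true(all(diff(at_t) < 0))
})

test_that("one-term reduction has the documented value, slope and accuracy", {
  a <- 0.0049
  g <- grain_geometry(a)
  expect_equal(one_term_mr(1e-8, g, 0), 6 / pi^2, tolerance = 1e-12)
  # log of the one-term solution is affine in t with slope -Deff pi^2 / a^2
  deff <- 4e-8
  tt <- seq(10, 500, by = 10)
  slope <- coef(lm(log(one_term_mr(deff, g, tt)) ~ tt))[[2]]
  expect_equal(slope, -deff * pi^2 / a^2, tolerance = 1e-10)
  # and that slope is exactly -k under the diffusivity bridge
  expect_equal(slope, -k_from_deff(deff, g), tolerance = 1e-10)
  # accuracy vs the full series, tabulated at Fourier-scaled times 1, 2, 5
  rel_err <- vapply(c(1, 2, 5), function(fo) {
    t_fo <- fo * a^2 / (deff * pi^2)
    full <- brute_sphere_mr(deff, a, t_fo)
    abs(one_term_mr(deff, g, t_fo) - full) / full
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))
  expect_lt(rel_err[1], 0.02)
  expect_lt(rel_err[2], 0.005)
  expect_lt(rel_err[3], 1e-6)
})

test_that("k <-> Deff bridge is exact, linear and lands in the reported band", {
  g <- grain_geometry(0.0049)
  res <- deff_from_k(0.0158, g)
  expect_equal(res$deff, 0.0158 * 0.0049^2 / pi^2, tolerance = 1e-15)
  expect_equal(res$deff_per_h, 60 * res$deff)
  expect_gt(res$deff_per_h, 2.26e-6)
  expect_lt(res$deff_per_h, 2.56e-6)
  expect_equal(res$deff_per_h, 2.306e-6, tolerance = 1e-3)
  # inverse identity and linearity
  set.seed(11)
  for (k in runif(10, 1e-4, 0.5)) {
    expect_equal(k_from_deff(deff_from_k(k, g)), k, tolerance = 1e-14)
  }
  expect_equal(k_from_deff(2 * res$deff, g), 2 * 0.0158, tolerance = 1e-12)
  expect_error(deff_from_k(0), "`k`")
  expect_error(k_from_deff(-1e-9), "`deff`")
})

test_that("moisture curve via Deff equals the k-parameterized curve", {
  g <- grain_geometry(0.0049)
  tt <- c(0, 15, 60, 120, 2600)
  for (p in random_params(8, seed = 23)) {
    deff <- deff_from_k(p$k, g)$deff
    expect_equal(moisture_via_deff(p$m0, p$me, deff, g, tt),
                 moisture_at_time(p, tt), tolerance = 1e-12)
  }
  p <- ref_params(0)
  deff <- deff_from_k(p$k)$deff
  expect_equal(moisture_via_deff(p$m0, p$me, deff, t = 0), p$m0)
  expect_equal(moisture_via_deff(p$m0, p$me, deff, t = 1e7), p$me,
               tolerance = 1e-10)
})

test_that("diffusivity rate vanishes at the endpoints and peaks at t = 1/k", {
  tt <- seq(0, 3000, by = 0.25)
  for (p in random_params(8, seed = 31)) {
    expect_identical(diffusivity_rate_vk(p, 0), 0)
    vk <- diffusivity_rate_vk(p, tt)
    expect_true(all(vk <= 0))
    t_star <- tt[which.max(abs(vk))]
    expect_equal(t_star, 1 / p$k, tolerance = 0.3 / (1 / p$k))
    expect_equal(vk_peak_time(p), 1 / p$k)
    expect_lt(abs(diffusivity_rate_vk(p, 3e5)), 1e-8)
  }
})

test_that("peak diffusivity-rate times of the five reference conditions precede 100 min", {
  for (st in ref_table$st_h) {
    t_star <- vk_peak_time(ref_params(st))
    expect_gt(t_star, 54)
    expect_lt(t_star, 100)
  }
})
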