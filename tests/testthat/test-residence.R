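test_that("limiting state patterns give the expected survival curves", {
  # molecule that never leaves
  s <- matrix(TRUE, 50, 3)
  cr <- residence_correlation(s, t_star = 0, dt = 0.1, lags = 0:25)
  expect_equal(cr$value, rep(1, 26))

  # molecule leaves permanently at frame k: origin 1 contributes 1 before,
  # 0 after
  s2 <- matrix(TRUE, 20, 1)
  s2[11:20, 1] <- FALSE
  cr2 <- residence_correlation(s2, t_star = 0, dt = 0.1, lags = 0:15,
                               origin_stride = 20)  # origin 1 only
  expect_equal(cr2$value, c(rep(1, 10), rep(0, 6)))
})

test_that("C_R equals the direct event-log oracle on exchange fixtures", {
  ex <- gen_shell_exchange(synthetic_spec("shell_exchange", n_particles = 25,
                                          n_frames = 120, dt = 0.1,
                                          k_out = 0.08, k_in = 0.05,
                                          box = make_box(40), seed = 21))
  lags <- c(0, 1, 2, 5, 10, 25, 60)
  for (ts in c(0, 0.25, 0.8)) {
    got <- residence_correlation(ex, t_star = ts, lags = lags)
    want <- oracle_residence(ex$states, 0.1, ts, lags)
    expect_equal(got$value, want, tolerance = 1e-12)
  }
})

test_that("C_R is monotone in lag and in the tolerance t*", {
  ex <- gen_shell_exchange(synthetic_spec("shell_exchange", n_particles = 60,
                                          n_frames = 200, dt = 0.1,
                                          k_out = 0.1, k_in = 0.08,
                                          box = make_box(40), seed = 5))
  prev <- NULL
  for (ts in c(0, 0.5, 1, 2)) {
    cr <- residence_correlation(ex, t_star = ts, lags = 0:100)
    expect_true(all(diff(cr$value) <= 1e-12))       # non-increasing in t
    if (!is.null(prev)) expect_true(all(cr$value >= prev - 1e-12))
    prev <- cr$value
  }
})

test_that("excursions shorter than t* do not change C_R", {
  base_spec <- synthetic_spec("shell_exchange", n_particles = 150,
                              n_frames = 300, dt = 0.1, k_out = 0.02, k_in = 0,
                              box = make_box(40), seed = 7)
  ctrl <- gen_shell_exchange(base_spec)
  with_ex <- gen_shell_exchange(synthetic_spec("shell_exchange",
                                               n_particles = 150, n_frames = 300,
                                               dt = 0.1, k_out = 0.02, k_in = 0,
                                               excursion_dur = 1,
                                               excursion_rate = 0.05,
                                               box = make_box(40), seed = 7))
  lags <- seq(0, 150, by = 5)
  cr_ctrl <- residence_correlation(ctrl, t_star = 2, lags = lags,
                                   origin_stride = 10)
  cr_ex <- residence_correlation(with_ex, t_star = 2, lags = lags,
                                 origin_stride = 10)
  # 1 ps excursions are strictly below t* = 2 ps: forgiven by construction,
  # up to the small state-stream perturbation they introduce
  expect_lt(max(abs(cr_ex$value - cr_ctrl$value)), 0.05)
  # with t* = 0 the same excursions do suppress the correlation
  cr_ex0 <- residence_correlation(with_ex, t_star = 0, lags = lags,
                                  origin_stride = 10)
  expect_lt(mean(cr_ex0$value), mean(cr_ex$value))
})

test_that("residence fits recover constructed and kinetic time constants", {
  t <- seq(0, 80, by = 0.2)
  y <- 0.3 * exp(-t / 2) + 0.7 * exp(-t / 13.1)
  fr <- fit_residence_times(tibble::tibble(time = t, value = y))
  expect_equal(fr$tau_residence, 13.1, tolerance = 0.01 * 13.1)
  expect_equal(fr$tau_escape, 2, tolerance = 0.01 * 2)

  # pure exponential: slow time recovered, degeneracy flagged
  fr1 <- fit_residence_times(tibble::tibble(time = t, value = exp(-t / 20)))
  expect_equal(fr1$tau_residence, 20, tolerance = 0.01 * 20)
  expect_true(fr1$degenerate)

  # exchange kinetics: escape rate 0.05/ps, no re-entry, t* = 0
  ex <- gen_shell_exchange(synthetic_spec("shell_exchange", n_particles = 300,
                                          n_frames = 1200, dt = 0.1,
                                          k_out = 0.05, k_in = 0,
                                          box = make_box(50), seed = 13))
  cr <- residence_correlation(ex, t_star = 0, lags = 0:600, origin_stride = 10)
  fr2 <- fit_residence_times(cr)
  expect_equal(fr2$tau_residence, 20, tolerance = 0.1 * 20)
})

test_that("the t* sweep reports curves and fits in long form", {
  ex <- gen_shell_exchange(synthetic_spec("shell_exchange", n_particles = 80,
                                          n_frames = 300, dt = 0.1,
                                          k_out = 0.05, k_in = 0.05,
                                          box = make_box(40), seed = 2))
  sw <- residence_tstar_sweep(ex, t_star_grid = c(0, 1, 2), lags = 0:150,
                              origin_stride = 10)
  expect_setequal(unique(sw$t_star), c(0, 1, 2))
  fits <- attr(sw, "fits")
  expect_equal(nrow(fits), 3)
  expect_true(all(is.finite(fits$tau_residence)))
})
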