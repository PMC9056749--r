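test_that("MSD matches the brute-force double-loop oracle", {
  set.seed(14)
  co <- array(cumsum(rnorm(5 * 60 * 3, sd = 0.4)), c(60, 5, 3))
  tr <- make_trajectory(co, 0.1 * (0:59), box = NULL, wrapped = FALSE)
  lags <- c(0, 1, 3, 7, 20, 59)
  got <- msd_layered(tr, lags = lags)
  expect_equal(got$msd, oracle_msd(co, lags), tolerance = 1e-12)
  expect_equal(got$time, lags * 0.1)
  expect_equal(got$msd[1], 0)
})

test_that("stationary and ballistic inputs give their closed-form MSDs", {
  co <- array(2, c(20, 3, 3))
  tr <- make_trajectory(co, 0.1 * (0:19), wrapped = FALSE)
  expect_true(all(msd_layered(tr)$msd == 0))

  # single particle with v = (1, 0, 0): MSD(t) = t^2 exactly
  t_grid <- 0.1 * (0:99)
  co2 <- array(0, c(100, 1, 3))
  co2[, 1, 1] <- t_grid
  tr2 <- make_trajectory(co2, t_grid, wrapped = FALSE)
  msd2 <- msd_layered(tr2, lags = c(0, 5, 20, 80))
  expect_equal(msd2$msd, msd2$time^2, tolerance = 1e-12)
})

test_that("layer restriction with the union of all layers equals no restriction", {
  set.seed(3)
  n <- 10
  top <- water_system_topology(n, n_solute = 1)
  L <- 25
  co <- array(0, c(30, 1 + 3 * n, 3))
  co[, 1, ] <- matrix(L / 2, 30, 3, byrow = TRUE)
  for (i in seq_len(n)) {
    base <- runif(3, 0, L)
    walk <- apply(matrix(rnorm(30 * 3, sd = 0.2), ncol = 3), 2, cumsum)
    o <- sweep(walk, 2, base, "+")
    co[, 1 + 3 * i - 2, ] <- o
    co[, 1 + 3 * i - 1, ] <- sweep(o, 2, c(0, 0.96, 0), "+")
    co[, 1 + 3 * i, ] <- sweep(o, 2, c(0.93, -0.24, 0), "+")
  }
  tr <- make_trajectory(co, 0.1 * (0:29), make_box(L), top)
  a <- assign_layers(wrap_trajectory(tr))
  un <- tr; un$wrapped <- FALSE
  lags <- c(0, 2, 5, 10)
  free <- msd_layered(un, lags = lags)
  restricted <- msd_layered(un, a, "all", lags = lags)
  expect_equal(restricted$msd, free$msd)
  # origin counts are reported and non-increasing with lag under continuity
  full_lags <- msd_layered(un, a, "0-4 A", lags = 0:20)
  cc <- full_lags$n_contrib[is.finite(full_lags$msd)]
  expect_true(all(diff(cc) <= 0))
})

test_that("power-law fits recover exact and simulated exponents", {
  t <- seq(0.1, 50, by = 0.1)
  msd6 <- tibble::tibble(time = t, msd = 6 * t)
  f <- fit_power_law(msd6)
  expect_equal(f$alpha, 1, tolerance = 1e-10)
  expect_equal(f$D, 6, tolerance = 1e-9)
  expect_equal(f$D_s, 1, tolerance = 1e-9)

  f2 <- fit_power_law(tibble::tibble(time = t, msd = t^2))
  expect_equal(f2$alpha, 2, tolerance = 1e-10)

  bro <- gen_brownian(synthetic_spec("brownian", n_particles = 200,
                                     n_frames = 2000, dt = 0.1, D = 0.2,
                                     box = make_box(100), seed = 5))
  fb <- fit_power_law(msd_layered(bro, origin_stride = 20))
  expect_equal(fb$alpha, 1, tolerance = 0.05)
  expect_equal(fb$D_s, 0.2, tolerance = 0.2 * 0.05)

  expect_error(fit_power_law(tibble::tibble(time = t[1:3], msd = 6 * t[1:3])),
               "fewer than 5")
  expect_error(fit_power_law(tibble::tibble(time = t, msd = 6 * t - 20)),
               "non-positive")
})

test_that("alpha estimates from disjoint particle subsets are consistent", {
  bro <- gen_brownian(synthetic_spec("brownian", n_particles = 100,
                                     n_frames = 800, dt = 0.1, D = 0.3,
                                     box = make_box(100), seed = 8))
  half1 <- bro; half1$coords <- bro$coords[, 1:50, , drop = FALSE]
  half2 <- bro; half2$coords <- bro$coords[, 51:100, , drop = FALSE]
  f1 <- fit_power_law(msd_layered(half1, origin_stride = 10))
  f2 <- fit_power_law(msd_layered(half2, origin_stride = 10))
  se <- sqrt(f1$alpha_se^2 + f2$alpha_se^2)
  expect_lt(abs(f1$alpha - f2$alpha), max(4 * se, 0.1))
})

test_that("regimes classify by alpha with a tolerance band", {
  expect_equal(classify_regime(1.0), "diffusive")
  expect_equal(classify_regime(0.87), "sub-diffusive")
  expect_equal(as.character(classify_regime(2.0)), "ballistic")
  expect_equal(classify_regime(1.53), "super-diffusive")
  # alpha = 1.99 sits inside the default ballistic band; with a tighter band
  # it is super-diffusive with a near-ballistic note
  expect_equal(as.character(classify_regime(1.99)), "ballistic")
  tight <- classify_regime(1.99, tolerance = 0.005)
  expect_equal(as.character(tight), "super-diffusive")
  expect_equal(attr(tight, "note"), "near_ballistic")
  expect_error(classify_regime(NaN), "finite")
})

test_that("the van Hove function is a normalized radial density", {
  bro <- gen_brownian(synthetic_spec("brownian", n_particles = 800,
                                     n_frames = 80, dt = 0.1, D = 0.25,
                                     box = make_box(100), seed = 6))
  vh <- van_hove_self(bro, lag_times = c(1, 3), breaks = 0.2,
                      origin_stride = 4)
  ints <- tapply(vh$density, vh$lag_time, function(d) sum(d) * 0.2)
  expect_true(all(abs(ints - 1) < 1e-6))
  expect_true(all(vh$density >= 0))

  # Brownian displacements follow the Gaussian radial closed form
  for (lt in c(1, 3)) {
    sl <- vh[vh$lag_time == lt, ]
    gauss <- 4 * pi * sl$r^2 * (4 * pi * 0.25 * lt)^(-3 / 2) *
      exp(-sl$r^2 / (4 * 0.25 * lt))
    expect_lt(max(abs(sl$density - gauss)), 0.15 * max(gauss))
    expect_lt(mean(abs(sl$density - gauss)), 0.04 * max(gauss))
  }

  # stationary particle: all probability in the first bin at every lag
  co <- array(5, c(30, 2, 3))
  tr <- make_trajectory(co, 0.1 * (0:29), wrapped = FALSE)
  vh0 <- van_hove_self(tr, lag_times = c(0.5, 2), breaks = 0.2)
  first <- vh0[vh0$r == min(vh0$r), ]
  expect_equal(first$density, rep(5, 2))  # 1 / bin width
  expect_equal(sum(vh0$density > 0), 2)
})

test_that("hop fixtures show a secondary van Hove mode that Brownian controls lack", {
  lev <- gen_levy_hop(synthetic_spec("levy_hop", n_particles = 250,
                                     n_frames = 250, dt = 0.1, ell = 8,
                                     tau_w = 10, box = make_box(60), seed = 4))
  vh <- van_hove_self(lev, lag_times = 10, breaks = 0.25, origin_stride = 5)
  modes <- van_hove_modes(vh)
  expect_true(any(modes$r >= 7 & modes$r <= 9))

  bro <- gen_brownian(synthetic_spec("brownian", n_particles = 250,
                                     n_frames = 250, dt = 0.1, D = 0.2,
                                     box = make_box(60), seed = 4))
  mb <- van_hove_modes(van_hove_self(bro, lag_times = 10, breaks = 0.25,
                                     origin_stride = 5))
  expect_false(any(mb$r >= 7 & mb$r <= 9))
})
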