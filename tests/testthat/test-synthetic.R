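test_that("generators are reproducible from (spec, seed) and stochastic across seeds", {
  sp <- synthetic_spec("brownian", n_particles = 5, n_frames = 50, dt = 0.1,
                       D = 0.2, seed = 11)
  expect_identical(gen_brownian(sp)$coords, gen_brownian(sp)$coords)
  sp2 <- synthetic_spec("brownian", n_particles = 5, n_frames = 50, dt = 0.1,
                        D = 0.2, seed = 12)
  expect_false(identical(gen_brownian(sp)$coords, gen_brownian(sp2)$coords))

  # per-particle streams: extending n_frames keeps earlier increments
  spL <- synthetic_spec("brownian", n_particles = 5, n_frames = 80, dt = 0.1,
                        D = 0.2, seed = 11)
  expect_equal(gen_brownian(spL)$coords[1:50, , ], gen_brownian(sp)$coords)

  # rotor: different seeds give different but statistically similar curves
  r1 <- gen_rotor(synthetic_spec("rotor", n_particles = 80, n_frames = 400,
                                 dt = 0.1, D_r = 0.05, seed = 1))
  r2 <- gen_rotor(synthetic_spec("rotor", n_particles = 80, n_frames = 400,
                                 dt = 0.1, D_r = 0.05, seed = 2))
  expect_false(identical(r1$u, r2$u))
  a1 <- dipole_acf(r1, lags = c(0, 20, 50), origin_stride = 10)
  a2 <- dipole_acf(r2, lags = c(0, 20, 50), origin_stride = 10)
  expect_equal(a1$value, a2$value, tolerance = 0.15)
})

test_that("degenerate parameter limits give exactly static dynamics", {
  b0 <- gen_brownian(synthetic_spec("brownian", n_particles = 4, n_frames = 30,
                                    dt = 0.1, D = 0, seed = 1))
  expect_equal(max(abs(apply(b0$coords, c(2, 3), function(v) diff(range(v))))), 0)

  v0 <- gen_ballistic(synthetic_spec("ballistic", n_particles = 4, n_frames = 30,
                                     dt = 0.1, speed = 0, seed = 1))
  msd <- msd_layered(v0)
  expect_true(all(msd$msd == 0))

  l0 <- gen_levy_hop(synthetic_spec("levy_hop", n_particles = 4, n_frames = 30,
                                    dt = 0.1, ell = 5, tau_w = Inf,
                                    box = make_box(30), seed = 1))
  expect_true(all(msd_layered(l0)$msd == 0))
  expect_equal(nrow(attr(l0, "ground_truth")$hops), 0)

  r0 <- gen_rotor(synthetic_spec("rotor", n_particles = 4, n_frames = 30,
                                 dt = 0.1, D_r = 0, seed = 1))
  ac <- dipole_acf(r0, lags = 0:29)
  expect_equal(ac$value, rep(1, 30), tolerance = 1e-12)
})

test_that("ballistic trajectories follow the exact closed form", {
  sp <- synthetic_spec("ballistic", n_particles = 1, n_frames = 100, dt = 0.1,
                       speed = 1, seed = 3)
  tr <- gen_ballistic(sp)
  v <- attr(tr, "ground_truth")$v
  msd <- msd_layered(tr, lags = c(0, 10, 50, 99))
  expect_equal(msd$msd, sum(v^2) * msd$time^2, tolerance = 1e-10)
})

test_that("logged hop events match the displacement record", {
  sp <- synthetic_spec("levy_hop", n_particles = 30, n_frames = 200, dt = 0.1,
                       ell = 6, tau_w = 4, box = make_box(40), seed = 9)
  tr <- gen_levy_hop(sp)
  hops <- attr(tr, "ground_truth")$hops
  # hop count equals the number of inter-frame displacement events > ell/2
  disp_events <- 0
  for (i in seq_len(30)) {
    d <- sqrt(rowSums((tr$coords[-1, i, ] - tr$coords[-200, i, ])^2))
    disp_events <- disp_events + sum(d > 3)
  }
  in_range <- hops$time <= tr$times[200]
  # several hops in one frame interval appear as one displacement event, and
  # the net may rarely fall below ell/2; tolerate the multi-hop deficit only
  expect_lte(disp_events, sum(in_range))
  expect_gte(disp_events, 0.8 * sum(in_range))
  expect_true(all(hops$length == 6))
})

test_that("the tetrahedral lattice saturates interior coordination", {
  lat <- gen_hb_lattice(synthetic_spec("hb_lattice", d_oo = 2.8, n_cells = 2,
                                       seed = 1))
  hb <- detect_hbonds(lat)
  interior <- attr(lat, "interior")
  expect_gt(length(interior), 0)
  for (m in interior) {
    expect_equal(sum(hb$donor_mol == m), 2)
    expect_equal(sum(hb$acceptor_mol == m), 2)
  }
  # corner molecules are under-coordinated
  all_mol <- water_molecules(lat$topology)
  corners <- setdiff(all_mol, interior)
  cnt <- vapply(corners, function(m)
    sum(hb$donor_mol == m) + sum(hb$acceptor_mol == m), numeric(1))
  expect_true(all(cnt < 4))

  # a 3.6 A lattice violates the O-O criterion everywhere
  lat36 <- gen_hb_lattice(synthetic_spec("hb_lattice", d_oo = 3.6, n_cells = 2,
                                         seed = 1), check_window = FALSE)
  expect_equal(nrow(detect_hbonds(lat36)), 0)
  expect_error(gen_hb_lattice(synthetic_spec("hb_lattice", d_oo = 3.6, seed = 1)),
               "window")
})

test_that("shell-exchange states follow the telegraph kinetics", {
  # no escape: correlation stays at 1
  ex0 <- gen_shell_exchange(synthetic_spec("shell_exchange", n_particles = 20,
                                           n_frames = 100, dt = 0.1, k_out = 0,
                                           k_in = 0, box = make_box(40), seed = 2))
  cr0 <- residence_correlation(ex0, t_star = 0, lags = 0:50)
  expect_equal(cr0$value, rep(1, 51))

  # escape rate 0.05/ps, no re-entry: survival ~ exp(-k t)
  ex <- gen_shell_exchange(synthetic_spec("shell_exchange", n_particles = 400,
                                          n_frames = 600, dt = 0.1, k_out = 0.05,
                                          k_in = 0, box = make_box(40), seed = 2))
  expect_equal(mean(ex$states[201, ]), exp(-0.05 * 20), tolerance = 0.1)
  # positions are consistent with the state: inside the shell iff in-state
  d <- minimum_image_distance(
    matrix(ex$trajectory$coords[50, 1, ], 400, 3, byrow = TRUE),
    matrix(ex$trajectory$coords[50, -1, ], ncol = 3), ex$trajectory$box)
  expect_true(all((d < 10) == ex$states[50, ]))
})
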