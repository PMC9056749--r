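# a water dimer with prescribed H...O and O...O distances: donor O at origin,
# its bonding H on the x axis, acceptor O on the same axis
water_dimer <- function(d_ho, d_oo, L = 30) {
  top <- water_system_topology(2)
  co <- array(0, c(1, 6, 3))
  c0 <- c(5, 5, 5)
  co[1, 1, ] <- c0                                   # donor O
  co[1, 2, ] <- c0 + c(d_oo - d_ho, 0, 0)            # donor H toward acceptor
  co[1, 3, ] <- c0 + c(-0.3, 0.9, 0)                 # other donor H
  co[1, 4, ] <- c0 + c(d_oo, 0, 0)                   # acceptor O
  co[1, 5, ] <- c0 + c(d_oo + 0.3, 0.9, 0)
  co[1, 6, ] <- c0 + c(d_oo + 0.3, -0.9, 0)
  make_trajectory(co, 0, make_box(L), top)
}

test_that("the distance criteria gate single hydrogen bonds", {
  hb <- detect_hbonds(water_dimer(2.4, 3.3))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_mol, 1)
  expect_equal(hb$acceptor_mol, 2)
  expect_equal(hb$d_ho, 2.4, tolerance = 1e-9)

  expect_equal(nrow(detect_hbonds(water_dimer(2.6, 3.3))), 0)  # H...O too long
  expect_equal(nrow(detect_hbonds(water_dimer(2.0, 3.6))), 0)  # O...O too long
  # thresholds are strict inequalities (distances exactly representable)
  expect_equal(nrow(detect_hbonds(water_dimer(2.5, 3.25))), 0)
  expect_equal(nrow(detect_hbonds(water_dimer(2.25, 3.5))), 0)
})

test_that("detection equals the all-pairs brute-force oracle on random fixtures", {
  for (seed in c(1, 7, 23, 99)) {
    tr <- random_water_traj(60, L = 14, seed = seed)
    got <- detect_hbonds(tr)
    got <- got[order(got$donor_mol, got$acceptor_mol, got$d_ho), ]
    want <- oracle_hbonds(tr)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want[order(want$donor_mol, want$acceptor_mol), ]
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$donor_mol, want$donor_mol)
      expect_equal(got$acceptor_mol, want$acceptor_mol)
    }
  }
})

test_that("hydrogen-bond counts are invariant under rigid motion and relabeling", {
  tr <- random_water_traj(40, L = 12, seed = 3)
  base <- detect_hbonds(tr)
  # rigid translation (then rewrap)
  tr2 <- tr
  tr2$coords[1, , ] <- tr$coords[1, , ] + matrix(c(3.1, -1.2, 7.7),
                                                 nrow = dim(tr$coords)[2],
                                                 ncol = 3, byrow = TRUE)
  tr2 <- wrap_trajectory(tr2)
  expect_equal(nrow(detect_hbonds(tr2)), nrow(base))
  # relabeling: reverse the order of molecules
  n <- 40
  perm <- unlist(lapply(n:1, function(i) c(3 * i - 2, 3 * i - 1, 3 * i)))
  tr3 <- tr
  tr3$coords[1, , ] <- tr$coords[1, perm, ]
  expect_equal(nrow(detect_hbonds(tr3)), nrow(base))
})

test_that("enabling the angle criterion never increases bond counts", {
  for (seed in c(2, 11)) {
    tr <- random_water_traj(50, L = 13, seed = seed)
    n_dist <- nrow(detect_hbonds(tr))
    n_ang <- nrow(detect_hbonds(tr, criteria = hbond_criteria(angle = 30)))
    expect_lte(n_ang, n_dist)
  }
  # lattice bonds are perfectly linear: the 30 degree criterion keeps them all
  lat <- gen_hb_lattice(synthetic_spec("hb_lattice", d_oo = 2.8, seed = 1))
  expect_equal(nrow(detect_hbonds(lat, criteria = hbond_criteria(angle = 30))),
               nrow(detect_hbonds(lat)))
})

test_that("per-layer n_HB averages match a direct per-frame count", {
  set.seed(31)
  tr <- random_water_traj(20, L = 10, n_frames = 3, seed = 13, jitter = 0.05)
  # single solute atom so layers are defined
  top <- water_system_topology(20, n_solute = 1)
  co <- array(0, c(3, 61, 3))
  co[, 1, ] <- matrix(5, 3, 3)
  co[, 2:61, ] <- tr$coords
  tr2 <- make_trajectory(co, tr$times, tr$box, top)
  a <- assign_layers(tr2, layer_spec(c(0, 20)))
  res <- nhb_per_layer(tr2, a)
  # oracle: per frame, count bonds per molecule by brute force
  per_frame_mean <- numeric(3)
  for (f in 1:3) {
    ob <- oracle_hbonds(tr2, frame = f)
    cnt <- numeric(20)
    if (!is.null(ob)) {
      for (i in seq_len(20)) {
        m <- i + 1  # molecule ids offset by the solute
        cnt[i] <- sum(ob$donor_mol == m) + sum(ob$acceptor_mol == m)
      }
    }
    per_frame_mean[f] <- mean(cnt)
  }
  expect_equal(res$nhb_mean[res$layer == "0-20 A"], mean(per_frame_mean),
               tolerance = 1e-10)
  expect_equal(res$nhb_sd[res$layer == "0-20 A"], sd(per_frame_mean),
               tolerance = 1e-10)
})

test_that("two isolated waters never bond", {
  tr <- water_dimer(4.5, 6.0)
  expect_equal(nrow(detect_hbonds(tr)), 0)
})

test_that("the intermittent bond correlation behaves as a conditional probability", {
  # two waters permanently bonded over 6 frames
  co <- array(0, c(6, 6, 3))
  d1 <- water_dimer(2.0, 3.0)
  for (f in 1:6) co[f, , ] <- d1$coords[1, , ]
  tr <- make_trajectory(co, 0.1 * (0:5), d1$box, d1$topology)
  ch <- hb_population_correlation(tr)
  expect_equal(ch$value, rep(1, 6))

  # bond present only at even-indexed frames: alternating 1, 0, 1, ...
  far <- water_dimer(4.5, 6.0)
  for (f in c(2, 4, 6)) co[f, , ] <- far$coords[1, , ]
  tr2 <- make_trajectory(co, 0.1 * (0:5), d1$box, d1$topology)
  ch2 <- hb_population_correlation(tr2)
  expect_equal(ch2$value, c(1, 0, 1, 0, 1, 0))

  expect_error(hb_population_correlation(far), "pair")
})

test_that("bond telegraph correlation matches the two-state closed form", {
  # two-state Markov bond indicator: P(on->off) = p, P(off->on) = q per frame.
  # conditional on h(0)=1: E h(t) = pi + (1-pi) lambda^t, lambda = 1-p-q,
  # pi = q/(p+q). Build a synthetic record table directly.
  set.seed(8)
  p <- 0.15; q <- 0.10; nf <- 400; np <- 200
  lambda <- 1 - p - q; pi1 <- q / (p + q)
  h <- matrix(FALSE, np, nf)
  h[, 1] <- runif(np) < pi1
  for (f in 2:nf) {
    stay <- runif(np)
    h[, f] <- ifelse(h[, f - 1], stay >= p, stay < q)
  }
  rec <- which(h, arr.ind = TRUE)
  records <- tibble::tibble(frame = rec[, 2],
                            donor_mol = rec[, 1], acceptor_mol = rec[, 1] + 1000,
                            class = "water-water")
  dummy <- water_dimer(2.0, 3.0)
  co <- array(dummy$coords[rep(1, nf), , ], c(nf, 6, 3))
  tr <- make_trajectory(co, 0.1 * seq_len(nf) - 0.1, dummy$box, dummy$topology)
  ch <- hb_population_correlation(tr, records = records, lags = c(0, 2, 5, 10, 20))
  expected <- pi1 + (1 - pi1) * lambda^c(0, 2, 5, 10, 20)
  expect_equal(ch$value, expected, tolerance = 0.05)
})

test_that("the double-exponential fitter recovers constructed lifetimes", {
  t <- seq(0, 60, by = 0.2)
  y <- 0.45 * exp(-t / 2.7) + 0.55 * exp(-t / 13.3)
  fit <- fit_double_exponential(tibble::tibble(time = t, value = y))
  expect_equal(fit$tau_fast, 2.7, tolerance = 0.01)
  expect_equal(fit$tau_slow, 13.3, tolerance = 0.01)
  expect_equal(fit$A, 0.45, tolerance = 0.01)
  expect_false(fit$degenerate)

  # single-exponential input is flagged degenerate, not failed
  y1 <- exp(-t / 5)
  fit1 <- fit_double_exponential(tibble::tibble(time = t, value = y1))
  expect_true(fit1$degenerate)

  # robustness to 1% additive noise (smaller replicate of the recovery study)
  set.seed(17)
  errs <- replicate(10, {
    yn <- y + rnorm(length(t), sd = 0.01)
    f <- fit_double_exponential(tibble::tibble(time = t, value = yn))
    abs(f$tau_slow - 13.3) / 13.3
  })
  expect_lt(median(errs), 0.05)
})

test_that("the hydration density map integrates to the mean water count", {
  set.seed(41)
  n <- 15
  top <- water_system_topology(n, n_solute = 4)
  L <- 20
  co <- array(0, c(4, 4 + 3 * n, 3))
  sol <- matrix(c(9, 9, 9, 11, 9, 9, 9, 11, 9, 9, 9, 11), ncol = 3, byrow = TRUE)
  for (f in 1:4) {
    co[f, 1:4, ] <- sol
    for (i in seq_len(n)) {
      o <- runif(3, 5, 15)
      co[f, 4 + 3 * i - 2, ] <- o
      co[f, 4 + 3 * i - 1, ] <- o + c(0, 0.96, 0)
      co[f, 4 + 3 * i, ] <- o + c(0.93, -0.24, 0)
    }
  }
  tr <- make_trajectory(co, 0.1 * (0:3), make_box(L), top)
  map <- hydration_density_map(tr, cutoff = 4, spacing = 0.5)
  # direct count oracle
  direct <- numeric(4)
  for (f in 1:4) {
    ow <- co[f, 4 + 3 * seq_len(n) - 2, ]
    dmin <- apply(ow, 1, function(p)
      min(vapply(1:4, function(s) sqrt(sum((p - sol[s, ])^2)), numeric(1))))
    direct[f] <- sum(dmin < 4)
  }
  expect_equal(sum(map$grid), mean(direct), tolerance = 1e-10)
  expect_equal(map$mean_count, mean(direct))

  # stationary single water inside: all weight in one voxel neighbourhood
  co1 <- co[, 1:7, , drop = FALSE]
  for (f in 1:4) {
    co1[f, 5, ] <- c(10, 10, 10.5); co1[f, 6, ] <- c(10, 10.9, 10.5)
    co1[f, 7, ] <- c(10.9, 9.8, 10.5)
  }
  tr1 <- make_trajectory(co1, 0.1 * (0:3), make_box(L),
                         water_system_topology(1, n_solute = 4))
  m1 <- hydration_density_map(tr1, cutoff = 4, spacing = 1)
  expect_equal(sum(m1$grid), 1)
  expect_equal(max(m1$grid), 1)  # a single voxel holds the whole weight
  # no waters in range: all-zero grid
  tr0 <- tr1
  tr0$coords[, 5:7, ] <- 1  # far corner
  m0 <- hydration_density_map(tr0, cutoff = 4, spacing = 1)
  expect_equal(sum(m0$grid), 0)
})
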