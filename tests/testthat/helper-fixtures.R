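# Shared fixtures and independent oracles. Oracles are deliberately naive
# (brute force, closed forms) and share no code with the package internals.

# random dilute water box: n 3-site waters with random rigid orientations
random_water_traj <- function(n_water, L = 20, n_frames = 1, seed = 1,
                              jitter = 0) {
  set.seed(seed)
  top <- water_system_topology(n_water)
  co <- array(0, c(n_frames, 3 * n_water, 3))
  base_o <- matrix(runif(3 * n_water, 0, L), ncol = 3)
  roh <- 0.9572; ang <- 104.52 * pi / 180
  for (f in seq_len(n_frames)) {
    for (i in seq_len(n_water)) {
      o <- base_o[i, ] + rnorm(3, sd = jitter)
      # random orthonormal frame
      q <- qr.Q(qr(matrix(rnorm(9), 3)))
      h1 <- o + roh * (cos(ang / 2) * q[, 1] + sin(ang / 2) * q[, 2])
      h2 <- o + roh * (cos(ang / 2) * q[, 1] - sin(ang / 2) * q[, 2])
      co[f, 3 * i - 2, ] <- o %% L
      co[f, 3 * i - 1, ] <- h1 %% L
      co[f, 3 * i, ] <- h2 %% L
    }
  }
  make_trajectory(co, times = 0.1 * (seq_len(n_frames) - 1), box = make_box(L),
                  topology = top)
}

# brute-force minimum-image distance over all 27 neighbour images
oracle_min_image <- function(a, b, L) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- sqrt(sum((b + c(i, j, k) * L - a)^2))
    best <- min(best, d)
  }
  best
}

# brute-force water-water hydrogen bonds: loop over every donor H and
# acceptor O, 27-image distances
oracle_hbonds <- function(traj, frame = 1, d_ho = 2.5, d_oo = 3.5) {
  top <- traj$topology
  L <- as.numeric(traj$box)
  xyz <- matrix(traj$coords[frame, , ], ncol = 3)
  hs <- which(top$role == "water-H")
  os <- which(top$role == "water-O")
  out <- NULL
  for (h in hs) {
    don_o <- os[top$mol_id[os] == top$mol_id[h]]
    for (o in os) {
      if (top$mol_id[o] == top$mol_id[h]) next
      dho <- oracle_min_image(xyz[h, ], xyz[o, ], L)
      doo <- oracle_min_image(xyz[don_o, ], xyz[o, ], L)
      if (dho < d_ho && doo < d_oo) {
        out <- rbind(out, data.frame(donor_mol = top$mol_id[h],
                                     acceptor_mol = top$mol_id[o]))
      }
    }
  }
  out
}

# vectorized variant of the hydrogen-bond brute force: distances enumerated
# explicitly over the 27 neighbour images (no minimum-image arithmetic).
# Returns "donor_mol donor_atom acceptor_mol" keys.
oracle_hbonds_vec <- function(traj, frame = 1, d_ho = 2.5, d_oo = 3.5) {
  top <- traj$topology
  L <- as.numeric(traj$box)
  xyz <- matrix(traj$coords[frame, , ], ncol = 3)
  hs <- which(top$role == "water-H")
  os <- which(top$role == "water-O")
  shifts <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
  img_dist <- function(p, pts) {
    best <- rep(Inf, nrow(pts))
    for (s in seq_len(27)) {
      d2 <- (pts[, 1] + shifts[s, 1] * L[1] - p[1])^2 +
        (pts[, 2] + shifts[s, 2] * L[2] - p[2])^2 +
        (pts[, 3] + shifts[s, 3] * L[3] - p[3])^2
      best <- pmin(best, d2)
    }
    sqrt(best)
  }
  keys <- character()
  o_xyz <- xyz[os, , drop = FALSE]
  for (h in hs) {
    don_o <- os[top$mol_id[os] == top$mol_id[h]]
    dho <- img_dist(xyz[h, ], o_xyz)
    doo <- img_dist(xyz[don_o, ], o_xyz)
    hit <- which(dho < d_ho & doo < d_oo & top$mol_id[os] != top$mol_id[h])
    if (length(hit)) {
      keys <- c(keys, paste(top$mol_id[h], top$id[h], top$mol_id[os[hit]]))
    }
  }
  keys
}

# brute-force MSD over all origins and molecules (unrestricted)
oracle_msd <- function(X, lags) {
  nf <- dim(X)[1]
  vapply(lags, function(lg) {
    tot <- 0; cnt <- 0
    for (o in seq_len(nf - lg)) {
      for (i in seq_len(dim(X)[2])) {
        tot <- tot + sum((X[o + lg, i, ] - X[o, i, ])^2)
        cnt <- cnt + 1
      }
    }
    tot / cnt
  }, numeric(1))
}

# direct evaluation of the residence correlation from a state series
oracle_residence <- function(states, dt, t_star, lags, origin_stride = 1) {
  nf <- nrow(states)
  vapply(lags, function(lg) {
    num <- 0; den <- 0
    for (o in seq(1, nf - lg, by = origin_stride)) {
      for (i in seq_len(ncol(states))) {
        if (!states[o, i]) next
        den <- den + 1
        if (!states[o + lg, i]) next
        # longest continuous absence strictly inside the window
        ok <- TRUE
        if (lg > 1) {
          run <- 0
          for (f in (o + 1):(o + lg - 1)) {
            run <- if (states[f, i]) 0 else run + 1
            if (run * dt >= t_star && run > 0) { ok <- FALSE; break }
          }
        }
        if (ok) num <- num + 1
      }
    }
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
}
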