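#' Specify a synthetic trajectory
#'
#' A `synthetic_spec` records every parameter (and the seed) of a generated
#' trajectory, so each generator is reproducible from the spec alone and the
#' spec can be serialized next to its outputs.
#'
#' @param kind One of `"brownian"`, `"ballistic"`, `"levy_hop"`, `"rotor"`,
#'   `"hb_lattice"`, `"shell_exchange"`, `"composite"`.
#' @param n_particles,n_frames,dt Trajectory dimensions; `dt` in ps.
#' @param box An `aqua_box` (or a length for a cubic box).
#' @param seed Integer RNG seed, recorded in the spec.
#' @param ... Kind-specific parameters (see the individual generators).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(kind, n_particles = 100, n_frames = 1000, dt = 0.1,
                           box = make_box(50), seed = 1, ...) {
  kinds <- c("brownian", "ballistic", "levy_hop", "rotor", "hb_lattice",
             "shell_exchange", "composite")
  if (!kind %in% kinds) stop("unknown kind: ", kind, call. = FALSE)
  if (!inherits(box, "aqua_box")) box <- make_box(box)
  extra <- list(...)
  num <- Filter(function(v) is.numeric(v) && length(v) == 1, extra)
  bad <- names(num)[vapply(num, function(v)
    v < 0 && !identical(v, -Inf), logical(1))]
  if (length(bad)) stop("negative parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(c(list(kind = kind, n_particles = n_particles, n_frames = n_frames,
                   dt = dt, box = box, seed = as.integer(seed)), extra),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> kind =", x$kind, "|", x$n_particles, "particles x",
      x$n_frames, "frames, dt =", x$dt, "ps, seed =", x$seed, "\n")
  invisible(x)
}

#' Write a synthetic spec as a YAML sidecar
#' @param spec A `synthetic_spec`.
#' @param path Output path.
#' @export
write_spec_yaml <- function(spec, path) {
  s <- unclass(spec)
  s$box <- as.numeric(s$box)
  yaml::write_yaml(s, path)
  invisible(path)
}

# Per-particle seed-derived RNG streams: particle i always sees the same
# increments regardless of how many other particles (or frames elsewhere)
# are generated first.
with_particle_seed <- function(seed, i, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((as.numeric(seed) * 100003 + i) %% .Machine$integer.max)
  expr
}

random_start <- function(n, box) {
  L <- unclass(box)
  cbind(stats::runif(n, 0, L[1]), stats::runif(n, 0, L[2]), stats::runif(n, 0, L[3]))
}

#' Generate Brownian (diffusive) trajectories
#'
#' Independent Gaussian increments per axis with variance `2 * D * dt`, so the
#' ensemble mean-squared displacement is `6 D t` (exponent alpha = 1).
#'
#' @param spec A `synthetic_spec` with `kind = "brownian"` and field `D`
#'   (Angstrom^2/ps).
#' @return An unwrapped `aqua_trajectory`; the spec is attached as attribute
#'   `"spec"` and the diffusion constant as ground truth.
#' @export
gen_brownian <- function(spec) {
  stopifnot(spec$kind == "brownian")
  D <- spec$D
  n <- spec$n_particles; nf <- spec$n_frames; dt <- spec$dt
  sd_inc <- sqrt(2 * D * dt)
  co <- array(0, c(nf, n, 3))
  start <- with_particle_seed(spec$seed, 0, random_start(n, spec$box))
  for (i in seq_len(n)) {
    # frame-major draw order so extending n_frames keeps earlier increments
    inc <- with_particle_seed(spec$seed, i,
      matrix(stats::rnorm(3 * (nf - 1), sd = sd_inc), ncol = 3, byrow = TRUE))
    co[, i, ] <- rbind(start[i, , drop = FALSE],
                       sweep(apply(inc, 2, cumsum), 2, start[i, ], "+"))
  }
  traj <- make_trajectory(co, times = dt * (seq_len(nf) - 1), box = spec$box,
                          topology = NULL, wrapped = FALSE)
  attr(traj, "spec") <- spec
  attr(traj, "ground_truth") <- list(D = D, alpha = 1)
  traj
}

#' Generate ballistic trajectories
#'
#' `r_i(t) = r_i(0) + v_i t` exactly, with isotropic random directions and
#' speeds drawn from `speed` (a single value, or a vector sampled uniformly),
#' so MSD(t) = <v^2> t^2 (alpha = 2).
#'
#' @param spec A `synthetic_spec` with `kind = "ballistic"` and field `speed`
#'   (Angstrom/ps; scalar or vector of candidate speeds).
#' @return An unwrapped `aqua_trajectory` with velocity ground truth attached.
#' @export
gen_ballistic <- function(spec) {
  stopifnot(spec$kind == "ballistic")
  n <- spec$n_particles; nf <- spec$n_frames; dt <- spec$dt
  start <- with_particle_seed(spec$seed, 0, random_start(n, spec$box))
  v <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    v[i, ] <- with_particle_seed(spec$seed, i, {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      s <- if (length(spec$speed) == 1) spec$speed else sample(spec$speed, 1)
      s * u
    })
  }
  t_grid <- dt * (seq_len(nf) - 1)
  co <- array(0, c(nf, n, 3))
  for (k in 1:3) co[, , k] <- outer(t_grid, v[, k]) +
    matrix(start[, k], nf, n, byrow = TRUE)
  traj <- make_trajectory(co, times = t_grid, box = spec$box,
                          topology = NULL, wrapped = FALSE)
  attr(traj, "spec") <- spec
  attr(traj, "ground_truth") <- list(v = v, msq_speed = mean(rowSums(v^2)), alpha = 2)
  traj
}

#' Generate Levy-hop (rest-and-jump) trajectories
#'
#' Particles rest at a site for an exponentially distributed waiting time
#' (mean `tau_w` ps), then jump instantaneously by a drawn length in a uniform
#' random direction. The default jump law is a fixed length `ell`; the
#' heavy-tailed option (`jump_law = "pareto"`, shape `pareto_alpha`) truncates
#' jumps at half the box length. All hop events are logged as ground truth.
#'
#' @param spec A `synthetic_spec` with `kind = "levy_hop"` and fields `ell`
#'   (Angstrom), `tau_w` (ps), optional `jump_law` and `pareto_alpha`.
#' @return An unwrapped `aqua_trajectory`; attribute `"ground_truth"$hops` is
#'   a tibble (particle, time, length).
#' @export
gen_levy_hop <- function(spec) {
  stopifnot(spec$kind == "levy_hop")
  n <- spec$n_particles; nf <- spec$n_frames; dt <- spec$dt
  L <- unclass(spec$box)
  jump_law <- spec$jump_law %||% "fixed"
  if (spec$ell >= min(L) / 2) {
    stop("jump length ell must be < L/2 (unwrapping precondition)", call. = FALSE)
  }
  t_end <- dt * (nf - 1)
  start <- with_particle_seed(spec$seed, 0, random_start(n, spec$box))
  co <- array(0, c(nf, n, 3))
  hops <- list()
  for (i in seq_len(n)) {
    sim <- with_particle_seed(spec$seed, i, {
      pos <- start[i, ]
      path <- matrix(pos, nf, 3, byrow = TRUE)
      t_now <- if (is.finite(spec$tau_w)) stats::rexp(1, 1 / spec$tau_w) else Inf
      ev <- NULL
      while (t_now <= t_end) {
        len <- if (jump_law == "fixed") spec$ell else {
          a <- spec$pareto_alpha %||% 1.5
          min(spec$ell * stats::runif(1)^(-1 / a), min(L) / 2 * 0.999)
        }
        u <- stats::rnorm(3); u <- len * u / sqrt(sum(u^2))
        pos <- pos + u
        fidx <- floor(t_now / dt) + 2L  # first frame at or after the hop
        if (fidx <= nf) path[fidx:nf, ] <- matrix(pos, nf - fidx + 1L, 3, byrow = TRUE)
        ev <- rbind(ev, c(t_now, len))
        t_now <- t_now + stats::rexp(1, 1 / spec$tau_w)
      }
      list(path = path, ev = ev)
    })
    co[, i, ] <- sim$path
    if (!is.null(sim$ev)) {
      hops[[length(hops) + 1L]] <- tibble::tibble(
        particle = i, time = sim$ev[, 1], length = sim$ev[, 2])
    }
  }
  traj <- make_trajectory(co, times = dt * (seq_len(nf) - 1), box = spec$box,
                          topology = NULL, wrapped = FALSE)
  attr(traj, "spec") <- spec
  attr(traj, "ground_truth") <- list(
    hops = if (length(hops)) dplyr::bind_rows(hops) else
      tibble::tibble(particle = integer(), time = numeric(), length = numeric()))
  traj
}

#' Generate unit-dipole rotors under isotropic rotational diffusion
#'
#' Each rotor's orientation performs a random walk on the unit sphere with
#' rotational diffusion constant `D_r` (1/ps), so the first-rank orientational
#' correlation is `<u(0).u(t)> = exp(-2 D_r t)` in expectation.
#'
#' @param spec A `synthetic_spec` with `kind = "rotor"` and field `D_r`. An
#'   optional `D_r_slow`/`n_slow` pair makes the first `n_slow` rotors use
#'   `D_r_slow` (two-population fixtures).
#' @return A list of class `rotor_series`: unit-vector array
#'   `n_frames x n_rotors x 3` plus times; spec and ground truth attached.
#' @export
gen_rotor <- function(spec) {
  stopifnot(spec$kind == "rotor")
  n <- spec$n_particles; nf <- spec$n_frames; dt <- spec$dt
  Dr <- rep(spec$D_r, n)
  if (!is.null(spec$n_slow) && spec$n_slow > 0) {
    Dr[seq_len(spec$n_slow)] <- spec$D_r_slow
  }
  u <- array(0, c(nf, n, 3))
  for (i in seq_len(n)) {
    u[, i, ] <- with_particle_seed(spec$seed, i, {
      sd_step <- sqrt(2 * Dr[i] * dt)
      ui <- stats::rnorm(3); ui <- ui / sqrt(sum(ui^2))
      out <- matrix(0, nf, 3)
      out[1, ] <- ui
      if (nf > 1) for (f in 2:nf) {
        g <- stats::rnorm(3, sd = sd_step)
        g <- g - sum(g * ui) * ui       # tangential kick
        ui <- ui + g
        ui <- ui / sqrt(sum(ui^2))
        out[f, ] <- ui
      }
      out
    })
  }
  structure(list(u = u, times = dt * (seq_len(nf) - 1)),
            spec = spec, ground_truth = list(D_r = Dr, tau_R = 1 / (2 * Dr)),
            class = "rotor_series")
}

#' Generate an ice-like tetrahedral water lattice
#'
#' Oxygen atoms occupy a diamond-cubic lattice with nearest-neighbour O-O
#' distance `d_oo`; each oxygen donates two hydrogens placed on donor O-O
#' axes 1.0 Angstrom from the donor, obeying the ice rules so every interior
#' molecule has exactly 4 hydrogen bonds (2 donated + 2 accepted) under the
#' geometric criteria when `d_oo` is within the bonding window.
#'
#' @param spec A `synthetic_spec` with `kind = "hb_lattice"`, field `d_oo`
#'   (Angstrom) and `n_cells` (unit cells per axis, default 2).
#' @param check_window Reject `d_oo` outside (2.5, 3.5) Angstrom? Default TRUE;
#'   disable to build deliberately non-bonding lattices.
#' @return A single-frame `aqua_trajectory` with water topology; attribute
#'   `"interior"` lists molecule ids with a complete 4-neighbour shell.
#' @export
gen_hb_lattice <- function(spec, check_window = TRUE) {
  stopifnot(spec$kind == "hb_lattice")
  d <- spec$d_oo
  if (check_window && (d <= 2.5 || d >= 3.5)) {
    stop("d_oo = ", d, " A is outside the hydrogen-bonding window (2.5, 3.5)",
         call. = FALSE)
  }
  nc <- spec$n_cells %||% 2L
  a <- 4 * d / sqrt(3)  # diamond cubic lattice constant
  fcc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  cells <- expand.grid(x = 0:(nc - 1), y = 0:(nc - 1), z = 0:(nc - 1))
  A <- do.call(rbind, lapply(seq_len(nrow(cells)), function(ci)
    sweep(fcc, 2, as.numeric(cells[ci, ]), "+"))) * a
  B <- sweep(A, 2, a / 4, "+")
  # sublattice-A neighbour offsets; A donates along t1, t2; B along -t3, -t4
  t1 <- c(1, 1, 1) * a / 4;  t2 <- c(1, -1, -1) * a / 4
  t3 <- c(-1, 1, -1) * a / 4; t4 <- c(-1, -1, 1) * a / 4
  O <- rbind(A, B)
  nA <- nrow(A)
  hw <- 1.0  # O-H bond length on the donor axis
  H <- matrix(0, 2 * nrow(O), 3)
  for (i in seq_len(nrow(O))) {
    dirs <- if (i <= nA) list(t1, t2) else list(-t3, -t4)
    for (k in 1:2) H[2 * (i - 1) + k, ] <- O[i, ] + hw * dirs[[k]] / sqrt(sum(dirs[[k]]^2))
  }
  nw <- nrow(O)
  co <- array(0, c(1, 3 * nw, 3))
  for (i in seq_len(nw)) {
    co[1, 3 * i - 2, ] <- O[i, ]
    co[1, 3 * i - 1, ] <- H[2 * i - 1, ]
    co[1, 3 * i, ]     <- H[2 * i, ]
  }
  top <- water_system_topology(nw)
  # non-periodic finite lattice: big box so minimum image is the identity
  span <- max(apply(co[1, , , drop = TRUE], 2, function(v) diff(range(v)))) + 4 * d
  off <- 2 * d - apply(co[1, , , drop = TRUE], 2, min)
  for (k in 1:3) co[1, , k] <- co[1, , k] + off[k]
  traj <- make_trajectory(co, times = 0, box = make_box(span), topology = top)
  # interior = all four diamond neighbours present
  all_t <- list(t1, t2, t3, t4)
  interior <- integer()
  for (i in seq_len(nw)) {
    nb <- if (i <= nA) lapply(all_t, function(tt) O[i, ] + tt)
          else lapply(all_t, function(tt) O[i, ] - tt)
    have <- vapply(nb, function(p)
      any(rowSums(sweep(O, 2, p)^2) < 1e-12), logical(1))
    if (all(have)) interior <- c(interior, i)
  }
  attr(traj, "spec") <- spec
  attr(traj, "interior") <- interior
  traj
}

#' Generate two-state shell-exchange trajectories
#'
#' Each particle carries a telegraph process between an "in" state (inside a
#' spherical shell of radius `r_shell` around a fixed dummy solute at the box
#' centre) and an "out" state, with escape rate `k_out` and re-entry rate
#' `k_in` (1/ps; `k_in = 0` disables re-entry). Optionally, brief excursions
#' of fixed duration `excursion_dur` ps are injected at rate `excursion_rate`
#' while in, to exercise the intermittency tolerance of residence analyses.
#'
#' @param spec A `synthetic_spec` with `kind = "shell_exchange"`, fields
#'   `k_out`, `k_in`, `r_shell` and optional `excursion_dur`, `excursion_rate`.
#' @return A list of class `exchange_series`: logical state matrix
#'   `n_frames x n_particles` (TRUE = in shell), a wrapped `aqua_trajectory`
#'   with a 1-atom dummy solute plus point particles, and times. The state
#'   series is the ground truth for recovery tests.
#' @export
gen_shell_exchange <- function(spec) {
  stopifnot(spec$kind == "shell_exchange")
  n <- spec$n_particles; nf <- spec$n_frames; dt <- spec$dt
  L <- unclass(spec$box)
  r_in <- spec$r_shell %||% (min(L) / 6)
  ex_dur <- spec$excursion_dur %||% 0
  ex_rate <- spec$excursion_rate %||% 0
  states <- matrix(FALSE, nf, n)
  for (i in seq_len(n)) {
    states[, i] <- with_particle_seed(spec$seed, i, {
      s <- logical(nf)
      s[1] <- TRUE
      cur <- TRUE
      p_out <- 1 - exp(-spec$k_out * dt)
      p_in <- 1 - exp(-spec$k_in * dt)
      p_ex <- if (ex_rate > 0) 1 - exp(-ex_rate * dt) else 0
      ex_frames <- max(1L, round(ex_dur / dt))
      f <- 2L
      while (f <= nf) {
        if (cur && p_ex > 0 && stats::runif(1) < p_ex) {
          # brief excursion: out for ex_frames, then back in
          upto <- min(nf, f + ex_frames - 1L)
          s[f:upto] <- FALSE
          f <- upto + 1L
          next
        }
        cur <- if (cur) stats::runif(1) >= p_out else stats::runif(1) < p_in
        s[f] <- cur
        f <- f + 1L
      }
      s
    })
  }
  centre <- L / 2
  co <- array(0, c(nf, n + 1L, 3))
  co[, 1, ] <- matrix(centre, nf, 3, byrow = TRUE)
  for (i in seq_len(n)) {
    dirs <- with_particle_seed(spec$seed, 100000L + i, {
      m <- matrix(stats::rnorm(3 * nf), ncol = 3)
      m / sqrt(rowSums(m^2))
    })
    rad <- ifelse(states[, i], r_in * 0.6, r_in * 2.0)
    co[, i + 1L, ] <- sweep(dirs * rad, 2, centre, "+")
  }
  top <- make_topology(tibble::tibble(
    id = seq_len(n + 1L),
    element = c("C", rep("O", n)),
    mass = c(12.011, rep(15.999, n)),
    charge = 0,
    mol_id = seq_len(n + 1L),
    role = c("solute", rep("ion", n))   # point particles, not 3-site waters
  ))
  traj <- make_trajectory(co, times = dt * (seq_len(nf) - 1), box = spec$box,
                          topology = top)
  structure(list(states = states, trajectory = traj,
                 times = dt * (seq_len(nf) - 1)),
            spec = spec,
            ground_truth = list(k_out = spec$k_out, k_in = spec$k_in,
                                tau_res = 1 / spec$k_out),
            class = "exchange_series")
}

#' Generate a composite solute + rigid-water system
#'
#' A small rigid dummy solute sits at the box centre; `n_particles` rigid
#' three-site waters (O-H 0.9572 Angstrom, H-O-H 104.52 degrees) move with
#' Brownian centre-of-mass motion (constant `D`) while their orientations
#' undergo rotational diffusion (constant `D_r`). This emulates the data
#' layout of a hydrated-solute MD run without any force field.
#'
#' @param spec A `synthetic_spec` with `kind = "composite"`, fields `D`, `D_r`
#'   and optional `n_solute` (default 8, a cube of dummy atoms of 3 Angstrom
#'   half-width).
#' @return A wrapped `aqua_trajectory` with full topology (solute group
#'   `"site"` = all solute atoms); ground truth `D`, `D_r` attached.
#' @export
gen_composite <- function(spec) {
  stopifnot(spec$kind == "composite")
  n <- spec$n_particles; nf <- spec$n_frames; dt <- spec$dt
  L <- unclass(spec$box)
  ns <- spec$n_solute %||% 8L
  centre <- L / 2
  # dummy solute: cube corners
  cube <- as.matrix(expand.grid(c(-3, 3), c(-3, 3), c(-3, 3)))[seq_len(ns), , drop = FALSE]
  sol <- sweep(cube, 2, centre, "+")
  # rigid water template in its molecular frame (COM at origin)
  roh <- 0.9572; ang <- 104.52 * pi / 180
  h1 <- roh * c(sin(ang / 2), cos(ang / 2), 0)
  h2 <- roh * c(-sin(ang / 2), cos(ang / 2), 0)
  mO <- 15.999; mH <- 1.008
  comO <- (mH * (h1 + h2)) / (mO + 2 * mH)  # O at origin; shift so COM at origin
  tmpl <- rbind(-comO, h1 - comO, h2 - comO)  # rows: O, H1, H2
  com <- array(0, c(nf, n, 3))
  start <- with_particle_seed(spec$seed, 0, random_start(n, spec$box))
  sd_inc <- sqrt(2 * spec$D * dt)
  co <- array(0, c(nf, ns + 3 * n, 3))
  for (f in seq_len(nf)) co[f, seq_len(ns), ] <- sol
  for (i in seq_len(n)) {
    walk <- with_particle_seed(spec$seed, i, {
      inc <- matrix(stats::rnorm(3 * (nf - 1), sd = sd_inc), ncol = 3, byrow = TRUE)
      rbind(start[i, , drop = FALSE],
            sweep(apply(inc, 2, cumsum), 2, start[i, ], "+"))
    })
    axes <- with_particle_seed(spec$seed, 200000L + i, {
      # orientation random walk: rotate the molecular frame by small random
      # rotations with angular variance 2*D_r*dt per axis
      R <- diag(3)
      out <- array(0, c(nf, 3, 3))
      out[1, , ] <- R
      sdr <- sqrt(2 * spec$D_r * dt)
      if (nf > 1) for (f in 2:nf) {
        w <- stats::rnorm(3, sd = sdr)
        R <- rotation_matrix(w) %*% R
        out[f, , ] <- R
      }
      out
    })
    for (f in seq_len(nf)) {
      sites <- tmpl %*% t(axes[f, , ]) + matrix(walk[f, ], 3, 3, byrow = TRUE)
      co[f, ns + 3 * i - 2:0, ] <- sites
    }
    com[, i, ] <- walk
  }
  # wrap molecules by their COM so waters stay intact across boundaries
  for (i in seq_len(n)) {
    for (k in 1:3) {
      shift <- floor(com[, i, k] / L[k]) * L[k]
      co[, ns + 3 * i - 2, k] <- co[, ns + 3 * i - 2, k] - shift
      co[, ns + 3 * i - 1, k] <- co[, ns + 3 * i - 1, k] - shift
      co[, ns + 3 * i, k]     <- co[, ns + 3 * i, k] - shift
    }
  }
  top <- water_system_topology(n, n_solute = ns,
                               groups = list(site = seq_len(ns)))
  traj <- make_trajectory(co, times = dt * (seq_len(nf) - 1), box = spec$box,
                          topology = top)
  attr(traj, "spec") <- spec
  attr(traj, "ground_truth") <- list(D = spec$D, D_r = spec$D_r)
  traj
}

# Rodrigues rotation matrix for rotation vector w (axis * angle)
rotation_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Dispatch a synthetic generator from its spec
#' @param spec A `synthetic_spec`.
#' @return The generator's output (see individual `gen_*` functions).
#' @export
generate <- function(spec) {
  switch(spec$kind,
    brownian = gen_brownian(spec),
    ballistic = gen_ballistic(spec),
    levy_hop = gen_levy_hop(spec),
    rotor = gen_rotor(spec),
    hb_lattice = gen_hb_lattice(spec),
    shell_exchange = gen_shell_exchange(spec),
    composite = gen_composite(spec))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
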