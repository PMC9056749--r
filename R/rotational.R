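#' Per-frame unit dipole vectors of the waters
#'
#' The molecular dipole is computed from topology partial charges and the
#' minimum-image geometry about each oxygen, then normalized to a unit vector
#' (for a rigid three-site water this is the H-O-H bisector direction).
#'
#' @param traj An `aqua_trajectory` with water roles and charges, or a
#'   `rotor_series` (returned unchanged).
#' @return A `rotor_series`: list with `u` (`n_frames x n_water x 3` unit
#'   vectors) and `times`.
#' @export
dipole_series <- function(traj) {
  if (inherits(traj, "rotor_series")) return(traj)
  top <- traj$topology
  wm <- water_molecules(top)
  nf <- n_frames(traj)
  u <- array(0, c(nf, length(wm), 3))
  oi <- vapply(wm, function(m) which(top$mol_id == m & top$role == "water-O"),
               integer(1))
  h1 <- vapply(wm, function(m) which(top$mol_id == m & top$role == "water-H")[1],
               integer(1))
  h2 <- vapply(wm, function(m) which(top$mol_id == m & top$role == "water-H")[2],
               integer(1))
  qO <- top$charge[oi]; q1 <- top$charge[h1]; q2 <- top$charge[h2]
  for (f in seq_len(nf)) {
    ro <- matrix(traj$coords[f, oi, ], ncol = 3)
    r1 <- matrix(traj$coords[f, h1, ], ncol = 3)
    r2 <- matrix(traj$coords[f, h2, ], ncol = 3)
    if (!is.null(traj$box) && traj$wrapped) {
      r1 <- ro + min_image_disp_rows(ro, r1, traj$box)
      r2 <- ro + min_image_disp_rows(ro, r2, traj$box)
    }
    # charges sum to ~0 per molecule, so the dipole is origin-independent;
    # computed about the oxygen
    mu <- q1 * (r1 - ro) + q2 * (r2 - ro)
    nrm <- sqrt(rowSums(mu^2))
    if (any(nrm < 1e-12)) stop("zero dipole for some water (charges all zero?)",
                               call. = FALSE)
    u[f, , ] <- mu / nrm
  }
  structure(list(u = u, times = traj$times), class = "rotor_series")
}

#' Dipole orientational correlation function
#'
#' First-rank correlation `C(t) = <u_i(t0) . u_i(t0 + t)>` averaged over time
#' origins and over molecules selected at the origin frame (origin-resident
#' selection, not continuous residence, so slowly relaxing interfacial waters
#' are not truncated by fast shell exchange). `C(0) = 1` for unit dipoles.
#' The second-rank (P2) correlation is available via `rank = 2`.
#'
#' @param dipoles A `rotor_series` (see [dipole_series()]) or an
#'   `aqua_trajectory`.
#' @param assignment,layer Optional origin-frame layer restriction.
#' @param select Optional `n_frames x n_water` logical matrix of per-origin
#'   selections (overrides `layer`).
#' @param lags Integer frame lags (default log-spaced).
#' @param origin_stride Origin spacing in frames.
#' @param rank Legendre rank, 1 (default) or 2.
#' @return A `corr_series` (time ps, value, n = contributing molecule-origins).
#' @export
dipole_acf <- function(dipoles, assignment = NULL, layer = NULL, select = NULL,
                       lags = NULL, origin_stride = 1, rank = 1) {
  dipoles <- dipole_series(dipoles)
  u <- dipoles$u
  nf <- dim(u)[1]
  dt <- dipoles$times[2] - dipoles$times[1]
  if (is.null(lags)) lags <- default_lag_grid(nf)
  lags <- sort(unique(as.integer(lags)))
  m <- if (!is.null(select)) select
       else if (!is.null(layer)) membership_matrix(assignment, layer)
       else NULL
  origins <- seq(1, nf, by = origin_stride)
  val <- numeric(length(lags)); cnt <- numeric(length(lags))
  for (li in seq_along(lags)) {
    lg <- lags[li]
    os <- origins[origins + lg <= nf]
    if (!length(os)) { val[li] <- NA; next }
    tot <- 0; n <- 0
    for (o in os) {
      dot <- u[o, , 1] * u[o + lg, , 1] + u[o, , 2] * u[o + lg, , 2] +
        u[o, , 3] * u[o + lg, , 3]
      if (!is.null(m)) dot <- dot[m[o, ]]
      if (rank == 2) dot <- 1.5 * dot^2 - 0.5
      tot <- tot + sum(dot)
      n <- n + length(dot)
    }
    if (n == 0) { val[li] <- NA; next }
    val[li] <- tot / n
    cnt[li] <- n
  }
  if (all(!is.finite(val) | cnt == 0)) {
    stop("selection is empty at every origin", call. = FALSE)
  }
  corr_series(time = lags * dt, value = val, n = cnt, label = "C(t) dipole")
}

#' Rotational relaxation time from a correlation function
#'
#' `tau_R = integral of C(t) dt`, evaluated by trapezoidal integration over
#' the sampled series plus an exponential-tail extrapolation fitted to the
#' final decade of positive decay; the tail contribution is reported
#' separately. A series whose tail has not decayed below 0.5 is rejected as
#' non-decaying.
#'
#' @param series A `corr_series` (or data frame with `time`, `value`).
#' @param floor_value Integration is truncated where `C(t)` first falls below
#'   this floor (default 0.02); beyond it the sampled correlation is noise
#'   and the analytic tail takes over.
#' @return A `relaxation_time` list: `tau_R` (ps), `tau_trapz`, `tau_tail`,
#'   `tau_exp_fit` (single-exponential alternative).
#' @export
relaxation_time <- function(series, floor_value = 0.02) {
  df <- tibble::as_tibble(series)[, c("time", "value")]
  df <- df[is.finite(df$value), ]
  tv <- df$time; cv <- df$value
  if (cv[length(cv)] > 0.5) {
    stop("correlation has not decayed (tail above 0.5): tau_R diverges",
         call. = FALSE)
  }
  # last reliable lag: where C first reaches the noise floor
  below <- which(cv < floor_value)
  cut <- if (length(below)) below[1] else length(cv)
  tv <- tv[seq_len(cut)]; cv <- cv[seq_len(cut)]
  tau_trapz <- sum(diff(tv) * (utils::head(cv, -1) + utils::tail(cv, -1)) / 2)
  # exponential tail: fit log C over the final decade before the cut
  tail_t0 <- max(tv) / 3
  sel <- tv >= tail_t0 & cv > 0
  tau_tail <- 0; tail_tau <- NA_real_
  if (sum(sel) >= 3) {
    tf <- stats::lm(log(cv[sel]) ~ tv[sel])
    slope <- unname(stats::coef(tf)[2])
    if (is.finite(slope) && slope < 0) {
      tail_tau <- -1 / slope
      c_end <- max(cv[length(cv)], 0)
      tau_tail <- c_end * tail_tau
    }
  }
  # single-exponential fit as the alternative convention
  pos <- cv > 0
  tau_exp <- tryCatch({
    f <- stats::lm(log(cv[pos]) ~ tv[pos])
    -1 / unname(stats::coef(f)[2])
  }, error = function(e) NA_real_)
  structure(list(tau_R = tau_trapz + tau_tail, tau_trapz = tau_trapz,
                 tau_tail = tau_tail, tail_tau = unname(tail_tau),
                 tau_exp_fit = unname(tau_exp)),
            class = "relaxation_time")
}

#' @export
print.relaxation_time <- function(x, ...) {
  cat("<relaxation_time> tau_R =", signif(x$tau_R, 4), "ps (trapezoid",
      signif(x$tau_trapz, 4), "+ tail", signif(x$tau_tail, 4), ")\n")
  invisible(x)
}

#' Site-resolved rotational relaxation
#'
#' Identical to [dipole_acf()] but selecting, at each origin frame, the waters
#' within `cutoff` of any atom of a named solute group (e.g. `"NH3"`, `"OH"`).
#'
#' @param traj A wrapped `aqua_trajectory` whose topology defines the group.
#' @param group Group name in `attr(topology, "groups")`.
#' @param cutoff Selection distance in Angstrom (default 4).
#' @param dipoles Optional precomputed `rotor_series`.
#' @param ... Passed to [dipole_acf()] (`lags`, `origin_stride`, `rank`).
#' @return A list: `acf` (`corr_series`), `tau` (`relaxation_time`),
#'   `mean_selected` waters per origin.
#' @export
site_resolved_tau <- function(traj, group, cutoff = 4, dipoles = NULL, ...) {
  top <- traj$topology
  gset <- attr(top, "groups")[[group]]
  if (is.null(gset)) stop("no group named '", group, "' in the topology", call. = FALSE)
  g_idx <- match(gset, top$id)
  wm <- water_molecules(top)
  oi <- vapply(wm, function(m) which(top$mol_id == m & top$role == "water-O"),
               integer(1))
  nf <- n_frames(traj)
  sel <- matrix(FALSE, nf, length(wm))
  for (f in seq_len(nf)) {
    dd <- min_image_cross_dist(matrix(traj$coords[f, oi, ], ncol = 3),
                               matrix(traj$coords[f, g_idx, ], ncol = 3),
                               traj$box)
    sel[f, ] <- apply(dd, 1, min) < cutoff
  }
  if (!any(sel)) stop("group '", group, "' is never hydrated within ", cutoff,
                      " A", call. = FALSE)
  if (is.null(dipoles)) dipoles <- dipole_series(traj)
  ac <- dipole_acf(dipoles, select = sel, ...)
  list(acf = ac, tau = relaxation_time(ac), mean_selected = mean(rowSums(sel)))
}
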