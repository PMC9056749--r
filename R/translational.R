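#' Coordinates used for displacement statistics
#'
#' Water systems use molecular centres of mass (computed from topology
#' masses); bare-particle fixtures use the raw coordinates. The trajectory
#' must be unwrapped first for displacement statistics.
#'
#' @param traj An `aqua_trajectory`.
#' @return Array `n_frames x n_molecules x 3`.
#' @export
displacement_coords <- function(traj) {
  top <- traj$topology
  if (!is.null(top) && any(top$role == "water-O")) water_com(traj)
  else traj$coords
}

default_lag_grid <- function(nf, n_lags = 60) {
  if (nf <= 2) return(seq_len(nf) - 1L)
  lg <- unique(c(0L, round(exp(seq(0, log(nf - 1), length.out = n_lags)))))
  sort(unique(pmin(lg, nf - 1L)))
}

#' Layer-restricted mean-squared displacement
#'
#' For each lag, averages `|r(t0 + t) - r(t0)|^2` over time origins and over
#' molecules passing the layer-membership rule at `(t0, lag)` (continuous
#' residence from `t0` to `t0 + t` by default, or endpoints only). Origin and
#' survivor counts are reported so sparse lags are visible; lags with no
#' surviving molecule are `NA`, not zero.
#'
#' @param traj An unwrapped `aqua_trajectory`.
#' @param assignment Optional `layer_assignment` (required unless
#'   `layer = "all"`).
#' @param layer Layer label or `"all"` (no restriction; the default).
#' @param rule `"continuous"` (default) or `"endpoints"` membership rule.
#' @param lags Integer frame lags (default: log-spaced grid).
#' @param origin_stride Origin spacing in frames (default 1).
#' @return An `msd_result`: tibble (lag, time, msd, n_origins, n_contrib) with
#'   attributes `layer`, `dt`, `origin_stride`.
#' @export
msd_layered <- function(traj, assignment = NULL, layer = "all",
                        rule = c("continuous", "endpoints"),
                        lags = NULL, origin_stride = 1) {
  rule <- match.arg(rule)
  if (traj$wrapped && !is.null(traj$box)) {
    warning("trajectory looks wrapped; unwrap_trajectory() first for MSD")
  }
  X <- displacement_coords(traj)
  nf <- dim(X)[1]
  dt <- traj_dt(traj)
  if (is.null(lags)) lags <- default_lag_grid(nf)
  lags <- sort(unique(as.integer(lags)))
  if (!identical(layer, "all")) {
    if (is.null(assignment)) stop("layer restriction needs an assignment", call. = FALSE)
    m <- membership_matrix(assignment, layer)
    cs <- apply(m, 2, cumsum)  # for continuous-residence window sums
  } else m <- NULL
  origins <- seq(1, nf, by = origin_stride)
  out <- tibble::tibble(lag = lags, time = lags * dt, msd = NA_real_,
                        n_origins = 0L, n_contrib = 0L)
  for (li in seq_along(lags)) {
    lg <- lags[li]
    os <- origins[origins + lg <= nf]
    if (!length(os)) next
    tot <- 0; cnt <- 0
    for (o in os) {
      d2 <- (X[o + lg, , 1] - X[o, , 1])^2 + (X[o + lg, , 2] - X[o, , 2])^2 +
        (X[o + lg, , 3] - X[o, , 3])^2
      if (!is.null(m)) {
        keep <- if (rule == "endpoints" || lg == 0) {
          m[o, ] & m[o + lg, ]
        } else if (o == 1) {
          cs[o + lg, ] == lg + 1
        } else {
          cs[o + lg, ] - cs[o - 1, ] == lg + 1
        }
        d2 <- d2[keep]
      }
      tot <- tot + sum(d2)
      cnt <- cnt + length(d2)
    }
    out$n_origins[li] <- length(os)
    out$n_contrib[li] <- cnt
    out$msd[li] <- if (cnt > 0) tot / cnt else NA_real_
  }
  structure(out, layer = layer, dt = dt, origin_stride = origin_stride,
            class = c("msd_result", class(out)))
}

#' Named fit windows for the generalized Einstein fit
#'
#' `"alpha1"` is the short-time window 0-0.3 ns (0-300 ps); `"alpha2"` the
#' long-time window 0.5-3 ns (500-3000 ps).
#'
#' @param name `"alpha1"` or `"alpha2"`.
#' @return Numeric `c(tmin, tmax)` in ps.
#' @export
fit_window <- function(name = c("alpha1", "alpha2")) {
  switch(match.arg(name), alpha1 = c(0, 300), alpha2 = c(500, 3000))
}

#' Fit the generalized Einstein power law MSD(t) = D t^alpha
#'
#' Unweighted least squares on `log MSD = log D + alpha log t` over the window
#' (t = 0 excluded). For a diffusive fit, `D_s = D / 6` is the self-diffusion
#' coefficient (MSD = 6 D_s t).
#'
#' @param msd An `msd_result` (or data frame with `time`, `msd`).
#' @param window `c(tmin, tmax)` in ps, or a preset name (`"alpha1"`,
#'   `"alpha2"`); default the full lag range.
#' @return A `power_law_fit`: `alpha`, `D`, `D_s`, `window`, `rss`,
#'   `n_points`, standard errors.
#' @export
fit_power_law <- function(msd, window = NULL) {
  df <- tibble::as_tibble(msd)[, c("time", "msd")]
  if (is.character(window)) window <- fit_window(window)
  if (!is.null(window)) df <- df[df$time >= window[1] & df$time <= window[2], ]
  df <- df[df$time > 0 & is.finite(df$msd), ]
  if (nrow(df) < 5) stop("fit window holds fewer than 5 valid MSD points", call. = FALSE)
  if (any(df$msd <= 0)) stop("non-positive MSD values in fit window", call. = FALSE)
  fit <- stats::lm(log(msd) ~ log(time), data = df)
  co <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))  # exact fits have ~0 rss
  structure(list(alpha = unname(co[2]), D = unname(exp(co[1])),
                 D_s = unname(exp(co[1])) / 6,
                 alpha_se = unname(se[2]),
                 window = window %||% range(df$time),
                 rss = sum(stats::residuals(fit)^2),
                 n_points = nrow(df), model = "power_law"),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("<power_law_fit> alpha =", signif(x$alpha, 4),
      "| D =", signif(x$D, 4), "A^2/ps^alpha",
      "| D_s = D/6 =", signif(x$D_s, 4), "A^2/ps",
      "|", x$n_points, "points in [", paste(signif(x$window, 4), collapse = ", "),
      "] ps\n")
  invisible(x)
}

#' Classify a dynamical regime from the exponent alpha
#'
#' `alpha = 1` is diffusive, `alpha < 1` sub-diffusive, `alpha > 1`
#' super-diffusive and `alpha = 2` ballistic, each within `tolerance`. A
#' super-diffusive exponent within 0.1 of 2 carries a `"near_ballistic"`
#' attribute as a note.
#'
#' @param alpha Fitted exponent (finite).
#' @param tolerance Half-width of the diffusive/ballistic bands (default 0.05).
#' @return Character regime label.
#' @export
classify_regime <- function(alpha, tolerance = 0.05) {
  if (!is.finite(alpha)) stop("alpha must be finite", call. = FALSE)
  lab <- if (abs(alpha - 2) <= tolerance) "ballistic"
    else if (abs(alpha - 1) <= tolerance) "diffusive"
    else if (alpha < 1) "sub-diffusive"
    else "super-diffusive"
  if (lab == "super-diffusive" && abs(alpha - 2) <= 0.1) {
    attr(lab, "note") <- "near_ballistic"
  }
  lab
}

#' Self van Hove function (radial displacement distribution)
#'
#' For each lag, the distribution of displacement magnitudes over molecules
#' and time origins, as a radial probability density (the 4 pi r^2-weighted
#' form): `integral G(r, t) dr = 1` per lag. An optional layer restriction
#' selects molecules resident at the origin frame.
#'
#' @param traj An unwrapped `aqua_trajectory`.
#' @param lag_times Lag times in ps (rounded to the frame grid).
#' @param breaks Radial bin edges in Angstrom, or a bin width (scalar).
#' @param assignment,layer Optional origin-frame layer restriction.
#' @param origin_stride Origin spacing in frames.
#' @return A `van_hove_result`: tibble (lag_time, r, density) with bin edges
#'   as attribute `breaks`.
#' @export
van_hove_self <- function(traj, lag_times, breaks = 0.2, assignment = NULL,
                          layer = NULL, origin_stride = 1) {
  X <- displacement_coords(traj)
  nf <- dim(X)[1]
  dt <- traj_dt(traj)
  lags <- unique(round(lag_times / dt))
  if (any(lags >= nf)) stop("lag times exceed the trajectory span", call. = FALSE)
  m <- if (!is.null(layer)) membership_matrix(assignment, layer) else NULL
  rows <- list()
  edges_by_lag <- list()
  for (lg in lags) {
    os <- seq(1, nf - lg, by = origin_stride)
    disp <- numeric(0)
    for (o in os) {
      d <- sqrt((X[o + lg, , 1] - X[o, , 1])^2 + (X[o + lg, , 2] - X[o, , 2])^2 +
                (X[o + lg, , 3] - X[o, , 3])^2)
      if (!is.null(m)) d <- d[m[o, ]]
      disp <- c(disp, d)
    }
    if (!length(disp)) stop("empty selection for the van Hove function", call. = FALSE)
    edges <- if (length(breaks) == 1) {
      seq(0, max(disp) + breaks, by = breaks)
    } else breaks
    hh <- graphics::hist(disp[disp <= max(edges)], breaks = edges, plot = FALSE)
    dens <- hh$counts / (length(disp) * diff(edges))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      lag_time = lg * dt, r = hh$mids, density = dens)
    edges_by_lag[[as.character(lg * dt)]] <- edges
  }
  out <- dplyr::bind_rows(rows)
  structure(out, breaks = edges_by_lag, dt = dt,
            class = c("van_hove_result", class(out)))
}

#' Detect secondary modes in a van Hove density
#'
#' Local maxima with prominence at least `prominence` times the main mode's
#' height, reported per lag. A secondary mode signals discrete translational
#' jumps (hopping).
#'
#' @param vh A `van_hove_result`.
#' @param prominence Minimum relative prominence (default 0.05).
#' @return Tibble: lag_time, r, density, rank (1 = main mode).
#' @export
van_hove_modes <- function(vh, prominence = 0.05) {
  vh |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$lag_time) |>
    dplyr::group_modify(function(df, key) {
      y <- df$density
      n <- length(y)
      if (n < 3) return(df[0, c("r", "density")])
      is_peak <- c(y[1] > y[2],
                   y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
                   y[n] > y[n - 1])
      pk <- which(is_peak)
      if (!length(pk)) return(df[0, c("r", "density")])
      main <- max(y[pk])
      # prominence: height above the deepest valley separating it from a
      # higher peak (or the series edge)
      prom <- vapply(pk, function(p) {
        left <- y[seq_len(p)]; right <- y[p:n]
        higher_l <- which(left > y[p]); higher_r <- which(right > y[p]) + p - 1L
        vl <- if (length(higher_l)) min(y[max(higher_l):p]) else min(left)
        vr <- if (length(higher_r)) min(y[p:min(higher_r)]) else min(right)
        y[p] - max(vl, vr)
      }, numeric(1))
      keep <- pk[prom >= prominence * main]
      res <- tibble::tibble(r = df$r[keep], density = y[keep])
      res[order(-res$density), ]
    }) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}
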