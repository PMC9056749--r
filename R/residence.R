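#' Residence-time correlation function with intermittency tolerance
#'
#' `C_R(t)` is the probability that a molecule in the region at the origin is
#' still (or again) there a lag `t` later without any continuous absence of
#' duration `t*` or longer in between: absences strictly shorter than `t*`
#' are forgiven as temporary excursions. `C_R(0) = 1` by construction
#' (the average conditions on presence at the origin) and `C_R` is
#' non-increasing in `t` and non-decreasing in `t*`.
#'
#' @param region An `exchange_series`, a logical `n_frames x n_molecules`
#'   matrix (TRUE = in region), or a `layer_assignment` (then give `layer`).
#' @param t_star Intermittency tolerance in ps (default 2).
#' @param dt Frame interval in ps (taken from `region` when it carries times).
#' @param layer Layer label when `region` is a `layer_assignment`.
#' @param lags Integer frame lags (default every frame up to half the series).
#' @param origin_stride Origin spacing in frames.
#' @return A `corr_series` (time ps, value, n = in-region origin molecules).
#' @export
residence_correlation <- function(region, t_star = 2, dt = NULL, layer = NULL,
                                  lags = NULL, origin_stride = 1) {
  if (inherits(region, "exchange_series")) {
    s <- region$states
    dt <- region$times[2] - region$times[1]
  } else if (inherits(region, "layer_assignment")) {
    if (is.null(layer)) stop("give a layer for a layer_assignment region", call. = FALSE)
    s <- membership_matrix(region, layer)
    dt <- region$times[2] - region$times[1]
  } else {
    s <- region
    if (is.null(dt)) stop("dt must be given for a bare state matrix", call. = FALSE)
  }
  nf <- nrow(s); n <- ncol(s)
  if (is.null(lags)) lags <- 0:(nf %/% 2)
  lags <- sort(unique(as.integer(lags)))
  # per molecule: frames belonging to a FALSE run that is NOT forgiven
  # (continuous absence of t_star or longer kills survival past its start)
  next_bad <- matrix(nf + 1L, nf, n)
  for (i in seq_len(n)) {
    r <- rle(s[, i])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad_starts <- starts[!r$values & r$lengths * dt >= t_star]
    nb <- rep(nf + 1L, nf)
    if (length(bad_starts)) {
      # next bad-run start at or after each frame
      idx <- findInterval(seq_len(nf) - 1L, bad_starts) + 1L
      nb <- ifelse(idx <= length(bad_starts), bad_starts[idx], nf + 1L)
    }
    next_bad[, i] <- nb
  }
  origins <- seq(1, nf, by = origin_stride)
  num <- den <- numeric(length(lags))
  for (o in origins) {
    in0 <- which(s[o, ])
    if (!length(in0)) next
    nb_o <- next_bad[o, in0]
    max_lag <- nf - o
    for (li in seq_along(lags)) {
      lg <- lags[li]
      if (lg > max_lag) break
      den[li] <- den[li] + length(in0)
      num[li] <- num[li] + sum(s[o + lg, in0] & (o + lg < nb_o))
    }
  }
  if (all(den == 0)) stop("region is empty at every origin", call. = FALSE)
  ok <- den > 0
  corr_series(time = lags[ok] * dt, value = num[ok] / den[ok], n = den[ok],
              label = paste0("C_R(t), t* = ", t_star, " ps"))
}

#' Fit residence and border-escape times from C_R(t)
#'
#' Double-exponential fit (shared machinery with the hydrogen-bond lifetime
#' fitter): the slow constant is the residence time, the fast one the escape
#' time of molecules at the region border.
#'
#' @param series A `corr_series` from [residence_correlation()].
#' @param window Optional `c(tmin, tmax)` ps.
#' @return A `residence_result`: `tau_residence`, `tau_escape` (ps),
#'   amplitude, rss, degenerate flag, and the underlying `biexp_fit`.
#' @export
fit_residence_times <- function(series, window = NULL) {
  fit <- fit_double_exponential(series, window = window)
  structure(list(tau_residence = fit$tau_slow, tau_escape = fit$tau_fast,
                 amplitude_fast = fit$A, rss = fit$rss,
                 degenerate = fit$degenerate, fit = fit),
            class = "residence_result")
}

#' @export
print.residence_result <- function(x, ...) {
  cat("<residence_result> residence time =", signif(x$tau_residence, 4), "ps",
      "| escape time =", signif(x$tau_escape, 4), "ps",
      if (x$degenerate) "(degenerate fit: effectively single-exponential)", "\n")
  invisible(x)
}

#' Sweep the intermittency tolerance t*
#'
#' Computes `C_R(t)` on a grid of `t*` values and, optionally, the fitted
#' residence time for each, as a diagnostic of the sensitivity of the
#' residence time to the tolerance.
#'
#' @inheritParams residence_correlation
#' @param t_star_grid Numeric vector of tolerances in ps.
#' @param fit Also fit residence times per t*? Default TRUE.
#' @return A long tibble (t_star, time, value, n) with, when `fit = TRUE`,
#'   a `fits` attribute tibble (t_star, tau_residence, tau_escape).
#' @export
residence_tstar_sweep <- function(region, t_star_grid = c(0, 1, 2, 4, 8),
                                  dt = NULL, layer = NULL, lags = NULL,
                                  origin_stride = 1, fit = TRUE) {
  curves <- lapply(t_star_grid, function(ts) {
    cr <- residence_correlation(region, t_star = ts, dt = dt, layer = layer,
                                lags = lags, origin_stride = origin_stride)
    dplyr::mutate(tibble::as_tibble(cr), t_star = ts, .before = 1)
  })
  out <- dplyr::bind_rows(curves)
  if (fit) {
    fits <- purrr::map_dfr(t_star_grid, function(ts) {
      cr <- out[out$t_star == ts, ]
      fr <- tryCatch(fit_residence_times(cr), error = function(e) NULL)
      tibble::tibble(t_star = ts,
                     tau_residence = fr$tau_residence %||% NA_real_,
                     tau_escape = fr$tau_escape %||% NA_real_)
    })
    attr(out, "fits") <- fits
  }
  out
}
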