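#' Geometric hydrogen-bond criteria
#'
#' A hydrogen bond exists when the intermolecular H...O distance is smaller
#' than `d_ho` and the O...O distance smaller than `d_oo` (strict
#' inequalities). An O-H/O-O angle cutoff is available but off by default:
#' with these distance cutoffs the sub-30-degree angle condition is implied
#' for water geometries.
#'
#' @param d_ho Maximum H...O (acceptor) distance, Angstrom. Default 2.5.
#' @param d_oo Maximum O...O distance, Angstrom. Default 3.5.
#' @param angle Maximum angle between the O-H and O-O vectors in degrees, or
#'   `NULL` (default) to disable the angle test. When enabled the conventional
#'   value is 30.
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(d_ho = 2.5, d_oo = 3.5, angle = NULL) {
  if (d_ho <= 0 || d_oo <= 0) stop("distance criteria must be positive", call. = FALSE)
  if (!is.null(angle) && (angle <= 0 || angle > 90)) {
    stop("angle criterion must be in (0, 90] degrees", call. = FALSE)
  }
  structure(list(d_ho = d_ho, d_oo = d_oo, angle = angle),
            class = "hbond_criteria")
}

#' Detect hydrogen bonds in one frame
#'
#' Reports every (donor H, acceptor O/N) pair meeting all enabled criteria,
#' using minimum-image distances. Water-water and water-solute bonds are both
#' returned, tagged by `class`: `"water-water"`, `"water-solute"` (water
#' donates to a solute N/O) or `"solute-water"` (a solute H donates to a water
#' O; the donor heavy atom is the nearest solute non-H atom within 1.3
#' Angstrom).
#'
#' @param traj An `aqua_trajectory` (wrapped) with water roles labelled.
#' @param frame Frame index (default 1).
#' @param criteria An `hbond_criteria`.
#' @return Tibble: frame, donor_mol, donor_atom, acceptor_mol, acceptor_atom,
#'   d_ho, d_oo, class.
#' @export
detect_hbonds <- function(traj, frame = 1, criteria = hbond_criteria()) {
  top <- traj$topology
  if (is.null(top)) stop("trajectory has no topology", call. = FALSE)
  xyz <- matrix(traj$coords[frame, , ], ncol = 3)
  box <- traj$box
  recs <- list()

  h_idx <- which(top$role == "water-H")
  ow_idx <- which(top$role == "water-O")
  # donor O of each water H (same molecule)
  donO_of_h <- vapply(h_idx, function(i)
    ow_idx[match(top$mol_id[i], top$mol_id[ow_idx])], integer(1))

  pairs_for <- function(don_h, don_heavy, acc, acc_class) {
    if (!length(don_h) || !length(acc)) return(NULL)
    d_ho <- min_image_cross_dist(xyz[don_h, , drop = FALSE],
                                 xyz[acc, , drop = FALSE], box)
    heavy_d <- min_image_cross_dist(xyz[unique(don_heavy), , drop = FALSE],
                                    xyz[acc, , drop = FALSE], box)
    d_oo <- heavy_d[match(don_heavy, unique(don_heavy)), , drop = FALSE]
    ok <- d_ho < criteria$d_ho & d_oo < criteria$d_oo
    # exclude intramolecular pairs
    same <- outer(top$mol_id[don_heavy], top$mol_id[acc], "==")
    ok <- ok & !same
    hit <- which(ok, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    hi <- don_h[hit[, 1]]; oi <- don_heavy[hit[, 1]]; ai <- acc[hit[, 2]]
    if (!is.null(criteria$angle)) {
      v_oh <- min_image_disp_rows(xyz[oi, , drop = FALSE], xyz[hi, , drop = FALSE], box)
      v_oo <- min_image_disp_rows(xyz[oi, , drop = FALSE], xyz[ai, , drop = FALSE], box)
      cosang <- rowSums(v_oh * v_oo) /
        (sqrt(rowSums(v_oh^2)) * sqrt(rowSums(v_oo^2)))
      keep <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi < criteria$angle
      hit <- hit[keep, , drop = FALSE]
      hi <- hi[keep]; oi <- oi[keep]; ai <- ai[keep]
      if (!length(hi)) return(NULL)
    }
    tibble::tibble(
      frame = frame,
      donor_mol = top$mol_id[oi], donor_atom = top$id[hi],
      acceptor_mol = top$mol_id[ai], acceptor_atom = top$id[ai],
      d_ho = d_ho[hit], d_oo = d_oo[hit], class = acc_class)
  }

  recs$ww <- pairs_for(h_idx, donO_of_h, ow_idx, "water-water")

  sol_acc <- which(top$role == "solute" & top$element %in% c("N", "O"))
  recs$ws <- pairs_for(h_idx, donO_of_h, sol_acc, "water-solute")

  sol_h <- which(top$role == "solute" & top$element == "H")
  if (length(sol_h)) {
    sol_heavy <- which(top$role == "solute" & top$element != "H")
    dd <- min_image_cross_dist(xyz[sol_h, , drop = FALSE],
                               xyz[sol_heavy, , drop = FALSE], box)
    near <- sol_heavy[apply(dd, 1, which.min)]
    bonded <- apply(dd, 1, min) < 1.3
    if (any(bonded)) {
      recs$sw <- pairs_for(sol_h[bonded], near[bonded], ow_idx, "solute-water")
    }
  }
  out <- dplyr::bind_rows(recs)
  if (!nrow(out)) {
    out <- tibble::tibble(frame = integer(), donor_mol = integer(),
                          donor_atom = integer(), acceptor_mol = integer(),
                          acceptor_atom = integer(), d_ho = numeric(),
                          d_oo = numeric(), class = character())
  }
  out
}

#' Detect hydrogen bonds in every frame
#' @inheritParams detect_hbonds
#' @param frames Frame indices (default all).
#' @return One tibble of records across frames.
#' @export
detect_hbonds_all <- function(traj, criteria = hbond_criteria(),
                              frames = seq_len(n_frames(traj))) {
  dplyr::bind_rows(lapply(frames, function(f) detect_hbonds(traj, f, criteria)))
}

#' Per-layer hydrogen-bond counts per water
#'
#' Counts each water's hydrogen bonds (donated + accepted, water-water by
#' default) toward the layer the water occupies that frame; returns the
#' time-averaged mean per resident water and the frame-to-frame standard
#' deviation of the per-frame layer mean. Frames where a layer is empty are
#' excluded from that layer's average.
#'
#' @param traj A wrapped `aqua_trajectory`.
#' @param assignment A `layer_assignment` for the same trajectory.
#' @param criteria An `hbond_criteria`.
#' @param records Optional precomputed `detect_hbonds_all()` output.
#' @param include_solute Also count water-solute bonds toward n_HB? Default
#'   FALSE (water-water only, the conventional n_HB).
#' @return Tibble: layer, nhb_mean, nhb_sd, n_frames_used, mean_population.
#' @export
nhb_per_layer <- function(traj, assignment, criteria = hbond_criteria(),
                          records = NULL, include_solute = FALSE) {
  if (is.null(records)) records <- detect_hbonds_all(traj, criteria)
  wm <- assignment$mol_id
  nf <- nrow(assignment$layer_matrix)
  labs <- assignment$spec$labels
  per_frame <- vector("list", nf)
  for (f in seq_len(nf)) {
    rf <- records[records$frame == f, , drop = FALSE]
    cnt <- stats::setNames(numeric(length(wm)), wm)
    ww <- rf[rf$class == "water-water", , drop = FALSE]
    if (nrow(ww)) {
      td <- table(factor(ww$donor_mol, levels = wm))
      ta <- table(factor(ww$acceptor_mol, levels = wm))
      cnt <- cnt + as.numeric(td) + as.numeric(ta)
    }
    if (include_solute) {
      ws <- rf[rf$class == "water-solute", , drop = FALSE]
      sw <- rf[rf$class == "solute-water", , drop = FALSE]
      if (nrow(ws)) cnt <- cnt + as.numeric(table(factor(ws$donor_mol, levels = wm)))
      if (nrow(sw)) cnt <- cnt + as.numeric(table(factor(sw$acceptor_mol, levels = wm)))
    }
    lay <- labs[assignment$layer_matrix[f, ]]
    per_frame[[f]] <- tibble::tibble(frame = f, layer = lay, nhb = cnt) |>
      dplyr::filter(!is.na(.data$layer)) |>
      dplyr::group_by(.data$layer) |>
      dplyr::summarise(mean_nhb = mean(.data$nhb), n = dplyr::n(), .groups = "drop")
  }
  dplyr::bind_rows(per_frame) |>
    dplyr::mutate(layer = factor(.data$layer, levels = labs)) |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(nhb_mean = mean(.data$mean_nhb),
                     nhb_sd = stats::sd(.data$mean_nhb),
                     n_frames_used = dplyr::n(),
                     mean_population = mean(.data$n), .groups = "drop")
}

#' Water-solute hydrogen-bond count, both normalizations
#'
#' Bonds between interfacial waters (first layer by default) and the solute,
#' reported per interfacial water molecule and per solute polar site (N, O and
#' polar H atoms), since either normalization is found in practice.
#'
#' @inheritParams nhb_per_layer
#' @param layer Layer restricting the waters (default the first layer label).
#' @return Tibble: per_water, per_polar_site, n_polar_sites, mean_bonds,
#'   mean_waters.
#' @export
water_solute_nhb <- function(traj, assignment, criteria = hbond_criteria(),
                             records = NULL, layer = NULL) {
  if (is.null(records)) records <- detect_hbonds_all(traj, criteria)
  if (is.null(layer)) layer <- assignment$spec$labels[1]
  top <- traj$topology
  n_polar <- sum(top$role == "solute" & top$element %in% c("N", "O", "H"))
  nf <- nrow(assignment$layer_matrix)
  lidx <- layer_index(assignment, layer)
  wm <- assignment$mol_id
  bonds <- waters <- numeric(nf)
  for (f in seq_len(nf)) {
    in_layer <- wm[which(assignment$layer_matrix[f, ] == lidx)]
    waters[f] <- length(in_layer)
    rf <- records[records$frame == f & records$class != "water-water", , drop = FALSE]
    wat_mol <- ifelse(rf$class == "water-solute", rf$donor_mol, rf$acceptor_mol)
    bonds[f] <- sum(wat_mol %in% in_layer)
  }
  keep <- waters > 0
  tibble::tibble(
    per_water = mean(bonds[keep] / waters[keep]),
    per_polar_site = mean(bonds) / max(n_polar, 1),
    n_polar_sites = n_polar,
    mean_bonds = mean(bonds),
    mean_waters = mean(waters))
}

# shared container for time-correlation functions
corr_series <- function(time, value, n = NA_integer_, label = NULL) {
  structure(tibble::tibble(time = time, value = value, n = n),
            label = label, class = c("corr_series", "tbl_df", "tbl", "data.frame"))
}

#' Intermittent hydrogen-bond population correlation
#'
#' `C_HB(t) = <h(0) h(t)> / <h(0)>` where `h(t) = 1` when a tagged molecule
#' pair is hydrogen-bonded at time `t`; the average runs over time origins and
#' over pairs bonded at the origin, so `C_HB(0) = 1`. Intermediate breaks are
#' allowed (intermittent correlation). Pairs are restricted by `pair_class`
#' and, optionally, to pairs whose donor water occupies `layer` at the origin.
#'
#' @param traj A wrapped `aqua_trajectory`.
#' @param criteria An `hbond_criteria`.
#' @param records Optional precomputed `detect_hbonds_all()` output.
#' @param pair_class `"water-water"` (default) or any tag from
#'   `detect_hbonds()`.
#' @param assignment,layer Optional layer restriction at the origin frame.
#' @param lags Frame lags to evaluate (default all).
#' @param origin_stride Origin spacing in frames (default 1).
#' @return A `corr_series` tibble (time ps, value, n = bonded origin pairs).
#' @export
hb_population_correlation <- function(traj, criteria = hbond_criteria(),
                                      records = NULL,
                                      pair_class = "water-water",
                                      assignment = NULL, layer = NULL,
                                      lags = NULL, origin_stride = 1) {
  if (is.null(records)) records <- detect_hbonds_all(traj, criteria)
  records <- records[records$class == pair_class, , drop = FALSE]
  nf <- n_frames(traj)
  dt <- traj_dt(traj)
  key <- paste(pmin(records$donor_mol, records$acceptor_mol),
               pmax(records$donor_mol, records$acceptor_mol))
  pairs <- unique(key)
  if (!length(pairs)) stop("no hydrogen-bonded pairs found", call. = FALSE)
  h <- matrix(FALSE, length(pairs), nf)
  h[cbind(match(key, pairs), records$frame)] <- TRUE
  if (!is.null(layer)) {
    stopifnot(!is.null(assignment))
    lidx <- layer_index(assignment, layer)
    don <- as.integer(sub(" .*", "", pairs))
    don_col <- match(don, assignment$mol_id)
    lay_ok <- assignment$layer_matrix[, don_col, drop = FALSE] == lidx
    lay_ok[is.na(lay_ok)] <- FALSE
  } else lay_ok <- NULL
  if (is.null(lags)) lags <- 0:(nf - 1)
  origins <- seq(1, nf, by = origin_stride)
  num <- den <- numeric(length(lags))
  for (li in seq_along(lags)) {
    lg <- lags[li]
    os <- origins[origins + lg <= nf]
    if (!length(os)) { num[li] <- NA; next }
    for (o in os) {
      h0 <- h[, o]
      if (!is.null(lay_ok)) h0 <- h0 & lay_ok[o, ]
      num[li] <- num[li] + sum(h0 & h[, o + lg])
      den[li] <- den[li] + sum(h0)
    }
  }
  if (all(den == 0, na.rm = TRUE)) stop("no bonded pairs at any origin", call. = FALSE)
  corr_series(time = lags * dt, value = num / den, n = den,
              label = paste0("C_HB(", pair_class, ")"))
}

#' Double-exponential decay fit
#'
#' Least-squares fit of `A exp(-t/tau_fast) + (1 - A) exp(-t/tau_slow)` with
#' `A` in `[0, 1]` and `tau_fast <= tau_slow` by convention, from multiple
#' starts spanning two decades of time constants (ties broken by lowest
#' residual). Degenerate fits (`tau_fast ~ tau_slow`, or `A` at a bound) are
#' flagged rather than failed.
#'
#' @param series A `corr_series` or data frame with `time` and `value`.
#' @param window Optional `c(tmin, tmax)` ps restricting the fit.
#' @param n_starts Number of multi-start initializations (default 8).
#' @return A `biexp_fit` object (see `tidy()`/`glance()` methods): amplitude
#'   `A` (fast share), `tau_fast`, `tau_slow` (ps), `rss`, `degenerate` flag.
#' @export
fit_double_exponential <- function(series, window = NULL, n_starts = 8) {
  df <- tibble::as_tibble(series)[, c("time", "value")]
  if (!is.null(window)) df <- df[df$time >= window[1] & df$time <= window[2], ]
  df <- df[is.finite(df$value), ]
  if (nrow(df) < 4) stop("too few points for a double-exponential fit", call. = FALSE)
  t_scale <- max(df$time[df$time > 0])
  resid_fn <- function(p) {
    p["A"] * exp(-df$time / p["tf"]) + (1 - p["A"]) * exp(-df$time / p["ts"]) -
      df$value
  }
  # starts: tau pairs spanning two decades, A in the middle; Levenberg-
  # Marquardt with box constraints (nls.lm tolerates boundary optima where a
  # formula-interface fit would report a singular Jacobian)
  taus <- exp(seq(log(t_scale / 100), log(t_scale), length.out = n_starts))
  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- c(A = 0.5, tf = taus[max(1, s - 2)] * 0.5, ts = taus[s])
    fit <- tryCatch(
      minpack.lm::nls.lm(st, fn = resid_fn,
                         lower = c(A = 0, tf = 1e-6, ts = 1e-6),
                         upper = c(A = 1, tf = 1e6 * t_scale, ts = 1e6 * t_scale),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("double-exponential fit failed to converge from all ",
                          n_starts, " starts", call. = FALSE)
  p <- best$fit$par
  A <- unname(p["A"]); tf <- unname(p["tf"]); ts <- unname(p["ts"])
  if (tf > ts) { tmp <- tf; tf <- ts; ts <- tmp; A <- 1 - A }
  # guard against an unidentified second component: keep the biexponential
  # only if it improves significantly (F-test) on the best single exponential
  single_resid <- function(p) p["a"] * exp(-df$time / p["tau"]) - df$value
  s_best <- NULL
  for (tau0 in taus) {
    sf <- tryCatch(
      minpack.lm::nls.lm(c(a = 1, tau = tau0), fn = single_resid,
                         lower = c(a = 0, tau = 1e-6),
                         upper = c(a = 2, tau = 1e6 * t_scale),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(sf) && (is.null(s_best) || sf$deviance < s_best$deviance)) {
      s_best <- sf
    }
  }
  single_preferred <- FALSE
  if (!is.null(s_best)) {
    rss1 <- s_best$deviance; rss2 <- best$rss
    fstat <- ((rss1 - rss2) / 1) / (rss2 / max(nrow(df) - 3, 1))
    insignificant <- !is.finite(fstat) ||
      stats::pf(fstat, 1, max(nrow(df) - 3, 1), lower.tail = FALSE) > 0.01
    # a slow constant is identifiable only with meaningful amplitude and a
    # value the fit window can actually resolve
    unresolved <- (1 - A) < 0.05 || A < 0.05 || ts > 0.6 * t_scale
    if (insignificant || unresolved) {
      single_preferred <- TRUE
      tf <- ts <- unname(s_best$par["tau"])
      A <- 1
      best$rss <- rss1
    }
  }
  degenerate <- single_preferred || (abs(log(ts / tf)) < 0.05) ||
    A < 1e-3 || A > 1 - 1e-3
  # amplitude at a bound: effectively single-exponential, the inactive time
  # constant is unidentified -- report the active one for both
  if (A < 1e-3) tf <- ts else if (A > 1 - 1e-3) ts <- tf
  structure(list(A = A, tau_fast = tf, tau_slow = ts, rss = best$rss,
                 n = nrow(df), window = window %||% range(df$time),
                 degenerate = degenerate, model = "biexponential"),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat("<biexp_fit> A =", signif(x$A, 4),
      "| tau_fast =", signif(x$tau_fast, 4), "ps",
      "| tau_slow =", signif(x$tau_slow, 4), "ps",
      "| rss =", signif(x$rss, 3),
      if (x$degenerate) "(degenerate: effectively single-exponential)", "\n")
  invisible(x)
}

#' Time-averaged 3-D hydration density map
#'
#' Frames are superposed onto the reference solute conformation (first frame
#' by default, proper-rotation Kabsch alignment on solute atoms); water
#' oxygens within `cutoff` of any solute atom are binned on a cubic grid in
#' the solute frame. Voxel values are mean counts per frame, so the grid
#' integral equals the mean water number within the cutoff.
#'
#' @param traj A wrapped `aqua_trajectory` with solute and waters.
#' @param cutoff Distance cutoff to the solute, Angstrom (default 4).
#' @param spacing Grid spacing, Angstrom (default 1).
#' @param reference Reference frame index for superposition (default 1).
#' @return A `density_map`: list with `grid` (3-D array of mean counts),
#'   `origin`, `spacing`, `mean_count`.
#' @export
hydration_density_map <- function(traj, cutoff = 4, spacing = 1, reference = 1) {
  if (spacing <= 0) stop("grid spacing must be positive", call. = FALSE)
  top <- traj$topology
  sol <- which(top$role == "solute")
  if (!length(sol)) stop("no solute atoms", call. = FALSE)
  ow <- which(top$role == "water-O")
  ref <- matrix(traj$coords[reference, sol, ], ncol = 3)
  ref_c <- colMeans(ref)
  lo <- apply(ref, 2, min) - cutoff - spacing
  hi <- apply(ref, 2, max) + cutoff + spacing
  dims <- pmax(1L, ceiling((hi - lo) / spacing))
  grid <- array(0, dims)
  nf <- n_frames(traj)
  total <- 0
  for (f in seq_len(nf)) {
    solf <- matrix(traj$coords[f, sol, ], ncol = 3)
    fit <- kabsch(solf, ref)
    wo <- matrix(traj$coords[f, ow, ], ncol = 3)
    if (!is.null(traj$box)) {
      # express waters in the solute's minimum image
      wo <- solf[rep(1, nrow(wo)), , drop = FALSE] +
        min_image_disp(solf[1, , drop = FALSE], wo, traj$box)
    }
    wt <- sweep(wo, 2, fit$centroid_mobile) %*% fit$rotation
    wt <- sweep(wt, 2, ref_c, "+")
    solt <- sweep(sweep(solf, 2, fit$centroid_mobile) %*% fit$rotation, 2, ref_c, "+")
    dmin <- apply(min_image_cross_dist(wt, solt, traj$box %||% make_box(1e6)), 1, min)
    inside <- which(dmin < cutoff)
    total <- total + length(inside)
    if (length(inside)) {
      ix <- floor(sweep(wt[inside, , drop = FALSE], 2, lo) / spacing) + 1L
      ok <- ix[, 1] >= 1 & ix[, 1] <= dims[1] & ix[, 2] >= 1 & ix[, 2] <= dims[2] &
        ix[, 3] >= 1 & ix[, 3] <= dims[3]
      ix <- ix[ok, , drop = FALSE]
      for (r in seq_len(nrow(ix))) {
        grid[ix[r, 1], ix[r, 2], ix[r, 3]] <- grid[ix[r, 1], ix[r, 2], ix[r, 3]] + 1
      }
    }
  }
  structure(list(grid = grid / nf, origin = lo, spacing = spacing,
                 mean_count = total / nf), class = "density_map")
}

#' Write a density map in OpenDX format
#' @param map A `density_map`.
#' @param path Output path.
#' @export
write_dx <- function(map, path) {
  d <- dim(map$grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", map$origin[1], map$origin[2], map$origin[3]),
    sprintf("delta %.4f 0 0", map$spacing),
    sprintf("delta 0 %.4f 0", map$spacing),
    sprintf("delta 0 0 %.4f", map$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  vals <- as.vector(aperm(map$grid, c(3, 2, 1)))  # x fastest-varying last in DX
  idx <- seq(1, length(vals), by = 3)
  for (i in idx) {
    writeLines(paste(sprintf("%.6g", vals[i:min(i + 2, length(vals))]),
                     collapse = " "), con)
  }
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
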