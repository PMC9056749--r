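#' Analysis configuration
#'
#' Collects every knob of the layer-resolved analysis with defaults matching
#' the standard interfacial-water protocol: 4-Angstrom layers out to 16
#' Angstrom, distance-only hydrogen-bond criteria (2.5 / 3.5 Angstrom),
#' power-law fit windows 0-0.3 ns and 0.5-3 ns, intermittency tolerance
#' t* = 2 ps. The config is validated on construction and serialized into
#' every output bundle.
#'
#' @param layer_edges Layer bin edges, Angstrom.
#' @param hb An `hbond_criteria`.
#' @param msd_windows Named list of `c(tmin, tmax)` ps fit windows.
#' @param t_star Residence intermittency tolerance, ps.
#' @param van_hove_lags Lag times for the van Hove function, ps (NULL skips).
#' @param site_groups Named groups to resolve rotational dynamics at
#'   (character vector of group names present in the topology).
#' @param site_cutoff Site-selection cutoff, Angstrom.
#' @param origin_stride Time-origin stride in frames for all correlations.
#' @param water_site `"O"` or `"com"` for layer assignment.
#' @param density_map Compute the 3-D hydration density map? Default FALSE.
#' @param hb_frames Max frames used for hydrogen-bond statistics (subsampled
#'   evenly; NULL = all).
#' @param seed RNG seed recorded for provenance (analyses are deterministic).
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(layer_edges = c(0, 4, 8, 12, 16),
                            hb = hbond_criteria(),
                            msd_windows = list(alpha1 = fit_window("alpha1"),
                                               alpha2 = fit_window("alpha2")),
                            t_star = 2,
                            van_hove_lags = NULL,
                            site_groups = character(),
                            site_cutoff = 4,
                            origin_stride = 1,
                            water_site = "O",
                            density_map = FALSE,
                            hb_frames = NULL,
                            seed = 1) {
  cfg <- list(layer_edges = layer_edges, hb = hb, msd_windows = msd_windows,
              t_star = t_star, van_hove_lags = van_hove_lags,
              site_groups = site_groups, site_cutoff = site_cutoff,
              origin_stride = origin_stride, water_site = water_site,
              density_map = density_map, hb_frames = hb_frames,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  if (any(diff(cfg$layer_edges) <= 0) || any(cfg$layer_edges < 0)) {
    stop("config error: layer_edges must be non-negative and increasing",
         call. = FALSE)
  }
  if (!inherits(cfg$hb, "hbond_criteria")) {
    stop("config error: hb must be an hbond_criteria", call. = FALSE)
  }
  if (cfg$t_star < 0) stop("config error: t_star must be >= 0", call. = FALSE)
  for (w in cfg$msd_windows) {
    if (length(w) != 2 || w[2] <= w[1]) {
      stop("config error: each msd_window must be c(tmin, tmax) with tmax > tmin",
           call. = FALSE)
    }
  }
  if (!cfg$water_site %in% c("O", "com")) {
    stop("config error: water_site must be 'O' or 'com'", call. = FALSE)
  }
  if (cfg$origin_stride < 1) stop("config error: origin_stride >= 1", call. = FALSE)
  invisible(cfg)
}

#' Read an analysis config from YAML
#' @param path YAML file; keys mirror [analysis_config()] arguments (the `hb`
#'   entry is a mapping with `d_ho`, `d_oo`, optional `angle`).
#' @return An `analysis_config`.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$hb)) y$hb <- do.call(hbond_criteria, y$hb)
  if (!is.null(y$msd_windows)) y$msd_windows <- lapply(y$msd_windows, as.numeric)
  do.call(analysis_config, y)
}

stage_error <- function(stage, e, bundle) {
  cond <- structure(
    class = c("aqua_stage_error", "error", "condition"),
    list(message = paste0("stage '", stage, "' failed: ", conditionMessage(e)),
         call = NULL, stage = stage, partial = bundle))
  stop(cond)
}

#' Run the full layer-resolved analysis
#'
#' Executes shells, hydrogen bonds, translational, rotational, residence and
#' solute-shape stages in order on one trajectory, producing a report bundle:
#' a per-layer summary table (n_HB mean and sd, alpha per window, tau_R,
#' residence and HB lifetime constants), the underlying correlation series,
#' and a run log with the full config. A stage failure aborts with a
#' stage-tagged error carrying the partial bundle (`condition$partial`).
#'
#' @param traj A wrapped `aqua_trajectory` with solute + water topology.
#' @param config An `analysis_config`.
#' @param output_dir Optional directory; when given, tables are written as
#'   CSV and the run log as YAML.
#' @return An `analysis_bundle`: list with `summary` (tibble), `series`,
#'   `shape`, `msd`, `fits`, `log`.
#' @export
run_analysis <- function(traj, config = analysis_config(), output_dir = NULL) {
  validate_config(config)
  bundle <- list(log = list(config = serialize_config(config),
                            n_frames = n_frames(traj),
                            n_atoms = n_atoms(traj),
                            dt_ps = traj_dt(traj),
                            started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                            stages = character()))
  done <- function(stage) bundle$log$stages <<- c(bundle$log$stages, stage)
  lspec <- layer_spec(config$layer_edges)
  labs <- lspec$labels
  os <- config$origin_stride

  # -- shells ---------------------------------------------------------------
  assignment <- tryCatch(
    assign_layers(traj, lspec, water_site = config$water_site),
    error = function(e) stage_error("shells", e, bundle))
  bundle$assignment <- assignment
  bundle$populations <- layer_populations(assignment)
  done("shells")

  # -- hydrogen bonds -------------------------------------------------------
  bundle <- tryCatch({
    frames <- seq_len(n_frames(traj))
    if (!is.null(config$hb_frames) && length(frames) > config$hb_frames) {
      frames <- unique(round(seq(1, length(frames), length.out = config$hb_frames)))
    }
    records <- detect_hbonds_all(traj, config$hb, frames = frames)
    sub_assign <- assignment
    sub_assign$layer_matrix <- assignment$layer_matrix[frames, , drop = FALSE]
    sub_records <- records
    sub_records$frame <- match(records$frame, frames)
    bundle$nhb <- nhb_per_layer(traj, sub_assign, config$hb, records = sub_records)
    bundle$nhb_solute <- water_solute_nhb(traj, sub_assign, config$hb,
                                          records = sub_records)
    bundle$hb_corr <- tryCatch(
      hb_population_correlation(traj, config$hb, records = records,
                                origin_stride = os),
      error = function(e) NULL)
    bundle$hb_lifetimes <- if (!is.null(bundle$hb_corr)) {
      tryCatch(fit_double_exponential(bundle$hb_corr), error = function(e) NULL)
    }
    if (isTRUE(config$density_map)) {
      bundle$density <- hydration_density_map(traj)
    }
    bundle
  }, error = function(e) stage_error("hbond", e, bundle))
  done("hbond")

  # -- translational --------------------------------------------------------
  bundle <- tryCatch({
    un <- unwrap_trajectory(traj)
    msd_list <- fits <- list()
    for (lay in labs) {
      msd_list[[lay]] <- msd_layered(un, assignment, lay, origin_stride = os)
      fits[[lay]] <- lapply(config$msd_windows, function(w) {
        tryCatch(fit_power_law(msd_list[[lay]], window = w),
                 error = function(e) NULL)
      })
    }
    bundle$msd <- msd_list
    bundle$alpha_fits <- fits
    if (!is.null(config$van_hove_lags)) {
      bundle$van_hove <- van_hove_self(un, config$van_hove_lags,
                                       origin_stride = os)
    }
    bundle
  }, error = function(e) stage_error("translational", e, bundle))
  done("translational")

  # -- rotational -----------------------------------------------------------
  bundle <- tryCatch({
    dip <- dipole_series(traj)
    rot <- list()
    for (lay in labs) {
      ac <- tryCatch(dipole_acf(dip, assignment, lay, origin_stride = os),
                     error = function(e) NULL)
      rot[[lay]] <- if (!is.null(ac)) {
        list(acf = ac, tau = tryCatch(relaxation_time(ac), error = function(e) NULL))
      }
    }
    bundle$rotational <- rot
    if (length(config$site_groups)) {
      bundle$site_tau <- lapply(stats::setNames(nm = config$site_groups),
        function(g) tryCatch(
          site_resolved_tau(traj, g, config$site_cutoff, dipoles = dip,
                            origin_stride = os),
          error = function(e) NULL))
    }
    bundle
  }, error = function(e) stage_error("rotational", e, bundle))
  done("rotational")

  # -- residence ------------------------------------------------------------
  bundle <- tryCatch({
    cr <- residence_correlation(assignment, t_star = config$t_star,
                                layer = labs[1], origin_stride = os)
    bundle$residence_corr <- cr
    bundle$residence <- tryCatch(fit_residence_times(cr), error = function(e) NULL)
    bundle
  }, error = function(e) stage_error("residence", e, bundle))
  done("residence")

  # -- solute shape ---------------------------------------------------------
  bundle <- tryCatch({
    bundle$shape <- shape_series(traj)
    bundle
  }, error = function(e) stage_error("solute_shape", e, bundle))
  done("solute_shape")

  bundle$summary <- bundle_summary(bundle, labs)
  bundle$log$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  class(bundle) <- "analysis_bundle"
  if (!is.null(output_dir)) write_bundle(bundle, output_dir)
  bundle
}

serialize_config <- function(cfg) {
  out <- unclass(cfg)
  out$hb <- unclass(out$hb)
  out$hb$angle <- out$hb$angle %||% "off"
  out
}

bundle_summary <- function(bundle, labs) {
  tau_of <- function(lay) {
    r <- bundle$rotational[[lay]]
    if (!is.null(r) && !is.null(r$tau)) r$tau$tau_R else NA_real_
  }
  alpha_of <- function(lay, win) {
    f <- bundle$alpha_fits[[lay]][[win]]
    if (!is.null(f)) f$alpha else NA_real_
  }
  nhb <- bundle$nhb
  win_names <- names(bundle$alpha_fits[[1]])
  tab <- tibble::tibble(layer = labs)
  tab$nhb_mean <- nhb$nhb_mean[match(labs, as.character(nhb$layer))]
  tab$nhb_sd <- nhb$nhb_sd[match(labs, as.character(nhb$layer))]
  for (w in win_names) {
    tab[[w]] <- vapply(labs, alpha_of, numeric(1), win = w)
  }
  tab$tau_R <- vapply(labs, tau_of, numeric(1))
  tab$tau_residence <- c(
    if (!is.null(bundle$residence)) bundle$residence$tau_residence else NA_real_,
    rep(NA_real_, length(labs) - 1))
  if (!is.null(bundle$hb_lifetimes)) {
    tab$hb_tau_fast <- bundle$hb_lifetimes$tau_fast
    tab$hb_tau_slow <- bundle$hb_lifetimes$tau_slow
  }
  tab
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("<analysis_bundle> stages:", paste(x$log$stages, collapse = " -> "), "\n")
  print(x$summary)
  invisible(x)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(bundle$populations, file.path(dir, "layer_populations.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$hb_corr)) {
    utils::write.csv(tibble::as_tibble(bundle$hb_corr),
                     file.path(dir, "hb_correlation.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$residence_corr)) {
    utils::write.csv(tibble::as_tibble(bundle$residence_corr),
                     file.path(dir, "residence_correlation.csv"), row.names = FALSE)
  }
  for (lay in names(bundle$msd)) {
    utils::write.csv(tibble::as_tibble(bundle$msd[[lay]]),
                     file.path(dir, paste0("msd_", gsub("[^0-9A-Za-z]+", "_", lay),
                                           ".csv")), row.names = FALSE)
  }
  if (!is.null(bundle$van_hove)) {
    utils::write.csv(tibble::as_tibble(bundle$van_hove),
                     file.path(dir, "van_hove.csv"), row.names = FALSE)
  }
  utils::write.csv(tibble::as_tibble(bundle$shape), file.path(dir, "shape.csv"),
                   row.names = FALSE)
  yaml::write_yaml(bundle$log, file.path(dir, "run_log.yaml"))
  if (!is.null(bundle$density)) write_dx(bundle$density, file.path(dir, "density.dx"))
  invisible(dir)
}

#' Run the built-in recovery validation suite
#'
#' Regenerates the synthetic ground-truth fixtures (ballistic and Brownian
#' exponents, Brownian diffusion constant, rotor relaxation time,
#' shell-exchange residence time, tetrahedral-lattice hydrogen-bond count)
#' and checks each recovered value against its expectation at the stated
#' tolerance.
#'
#' @param seed Integer seed for all generators.
#' @param scale Size multiplier (1 = standard desk-scale sizes).
#' @return Tibble: statistic, expected, recovered, tolerance (relative),
#'   pass; attribute `"pass"` is the overall verdict.
#' @export
run_validation_suite <- function(seed = 1, scale = 1) {
  rows <- list()
  add <- function(stat, expected, recovered, tol) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      statistic = stat, expected = expected, recovered = recovered,
      tolerance = tol,
      pass = abs(recovered - expected) <= tol * max(abs(expected), 1e-12))
  }

  bal <- gen_ballistic(synthetic_spec("ballistic", n_particles = round(100 * scale),
                                      n_frames = 500, dt = 0.1, speed = c(0.5, 1, 2),
                                      box = make_box(200), seed = seed))
  f <- fit_power_law(msd_layered(bal, origin_stride = 10))
  add("ballistic alpha", 2, f$alpha, 0.01)

  bro <- gen_brownian(synthetic_spec("brownian", n_particles = round(200 * scale),
                                     n_frames = 2000, dt = 0.1, D = 0.2,
                                     box = make_box(100), seed = seed))
  msd <- msd_layered(bro, origin_stride = 20)
  fb <- fit_power_law(msd)
  add("brownian alpha", 1, fb$alpha, 0.05)
  add("brownian D_s", 0.2, fb$D_s, 0.05)

  rot <- gen_rotor(synthetic_spec("rotor", n_particles = round(400 * scale),
                                  n_frames = 4000, dt = 0.1, D_r = 0.025,
                                  seed = seed))
  ac <- dipole_acf(rot, lags = seq(0, 1500, by = 5), origin_stride = 40)
  tr <- relaxation_time(ac)
  add("rotor tau_R", 20, tr$tau_R, 0.10)

  ex <- gen_shell_exchange(synthetic_spec("shell_exchange",
                                          n_particles = round(500 * scale),
                                          n_frames = 1200, dt = 0.1,
                                          k_out = 0.05, k_in = 0,
                                          box = make_box(60), seed = seed))
  cr <- residence_correlation(ex, t_star = 0, lags = seq(0, 400, by = 2),
                              origin_stride = 10)
  fr <- fit_residence_times(cr)
  add("exchange residence time", 20, fr$tau_residence, 0.10)

  lat <- gen_hb_lattice(synthetic_spec("hb_lattice", d_oo = 2.8, n_cells = 2,
                                       seed = seed))
  hb <- detect_hbonds(lat)
  interior <- attr(lat, "interior")
  cnt <- vapply(interior, function(m) {
    sum(hb$donor_mol == m) + sum(hb$acceptor_mol == m)
  }, numeric(1))
  add("lattice interior n_HB", 4, mean(cnt), 0)

  out <- dplyr::bind_rows(rows)
  attr(out, "pass") <- all(out$pass)
  out
}
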