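#' Define hydration layers
#'
#' Layers are half-open distance bins `[e_k, e_{k+1})` of minimum distance to
#' any solute atom; beyond the last edge the label is `"bulk"`. The default
#' edges are four 4-Angstrom layers out to 16 Angstrom, past which bulk
#' behaviour holds.
#'
#' @param edges Strictly increasing, non-negative bin edges in Angstrom.
#' @return A list of class `layer_spec` with `edges` and `labels`.
#' @export
layer_spec <- function(edges = c(0, 4, 8, 12, 16)) {
  edges <- as.numeric(edges)
  if (any(edges < 0) || any(diff(edges) <= 0)) {
    stop("layer edges must be non-negative and strictly increasing", call. = FALSE)
  }
  labels <- paste0(utils::head(edges, -1), "-", utils::tail(edges, -1), " A")
  structure(list(edges = edges, labels = c(labels, "bulk")), class = "layer_spec")
}

#' Assign waters to hydration layers, every frame
#'
#' For each water and frame, the minimum over solute atoms of the
#' minimum-image distance to the chosen water site (oxygen by default, or the
#' centre of mass) is binned into the layer spec's half-open bins.
#'
#' @param traj A wrapped `aqua_trajectory` with a topology containing at least
#'   one solute atom and a periodic box.
#' @param spec A `layer_spec`.
#' @param water_site `"O"` (default; the distance criterion is atomic) or
#'   `"com"`.
#' @return A `layer_assignment`: list with `table` (tibble: frame, mol_id,
#'   distance, layer), `layer_matrix` (frames x waters factor codes),
#'   `dist_matrix`, `spec`, `mol_id`, `times`.
#' @export
assign_layers <- function(traj, spec = layer_spec(), water_site = c("O", "com")) {
  water_site <- match.arg(water_site)
  top <- traj$topology
  if (is.null(top)) stop("trajectory has no topology", call. = FALSE)
  sol_idx <- which(top$role == "solute")
  if (!length(sol_idx)) stop("topology contains no solute atoms", call. = FALSE)
  if (is.null(traj$box)) stop("layer assignment needs a periodic box", call. = FALSE)
  nf <- n_frames(traj)
  if (any(top$role == "water-O")) {
    wm <- water_molecules(top)
    site <- if (water_site == "com") {
      water_com(traj)
    } else {
      oi <- vapply(wm, function(m)
        which(top$mol_id == m & top$role == "water-O"), integer(1))
      traj$coords[, oi, , drop = FALSE]
    }
  } else {
    # point-particle fixtures: every non-solute atom is its own "water"
    wi <- which(top$role != "solute")
    wm <- top$mol_id[wi]
    site <- traj$coords[, wi, , drop = FALSE]
  }
  nw <- length(wm)
  dmat <- matrix(0, nf, nw)
  for (f in seq_len(nf)) {
    pts <- matrix(site[f, , ], ncol = 3)
    dd <- min_image_cross_dist(pts, matrix(traj$coords[f, sol_idx, ], ncol = 3),
                               traj$box)
    dmat[f, ] <- apply(dd, 1, min)
  }
  nlay <- length(spec$labels)
  lmat <- matrix(findInterval(dmat, spec$edges), nf, nw)  # 0 below first edge
  lmat[dmat < spec$edges[1]] <- NA_integer_               # below-range: unassigned
  tab <- tibble::tibble(
    frame = rep(seq_len(nf), times = nw),
    time = rep(traj$times, times = nw),
    mol_id = rep(wm, each = nf),
    distance = as.vector(dmat),
    layer = factor(spec$labels[as.vector(lmat)], levels = spec$labels)
  )
  structure(list(table = tab, layer_matrix = lmat, dist_matrix = dmat,
                 spec = spec, mol_id = wm, times = traj$times),
            class = "layer_assignment")
}

#' @export
print.layer_assignment <- function(x, ...) {
  cat("<layer_assignment> ", length(x$mol_id), " waters x ",
      nrow(x$layer_matrix), " frames\n", sep = "")
  print(layer_populations(x))
  invisible(x)
}

#' Per-layer mean populations
#' @param assignment A `layer_assignment`.
#' @return Tibble with layer, mean and sd of the per-frame population.
#' @export
layer_populations <- function(assignment) {
  assignment$table |>
    dplyr::count(.data$frame, .data$layer, .drop = FALSE) |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(mean_n = mean(.data$n), sd_n = stats::sd(.data$n),
                     .groups = "drop")
}

layer_index <- function(assignment, layer) {
  if (identical(layer, "all")) return(NA_integer_)
  idx <- match(layer, assignment$spec$labels)
  if (is.na(idx)) stop("unknown layer '", layer, "'; available: ",
                       paste(assignment$spec$labels, collapse = ", "),
                       call. = FALSE)
  idx
}

# logical frames x waters membership matrix for one layer (or all)
membership_matrix <- function(assignment, layer) {
  if (identical(layer, "all")) {
    matrix(TRUE, nrow(assignment$layer_matrix), ncol(assignment$layer_matrix))
  } else {
    idx <- layer_index(assignment, layer)
    m <- assignment$layer_matrix == idx
    m[is.na(m)] <- FALSE
    m
  }
}

#' Continuous-residence membership mask
#'
#' TRUE for waters that are in `layer` at every frame from `t0_index` through
#' `t0_index + lag` (the continuous-residence reading of layer-restricted
#' statistics). The alternative, endpoints-only rule is exposed via
#' `rule = "endpoints"`.
#'
#' @param assignment A `layer_assignment`.
#' @param layer A layer label (see `layer_spec()$labels`) or `"all"`.
#' @param t0_index Origin frame (1-based).
#' @param lag Lag in frames (>= 0).
#' @param rule `"continuous"` (default) or `"endpoints"`.
#' @return Logical vector over waters.
#' @export
continuous_membership_mask <- function(assignment, layer, t0_index, lag,
                                       rule = c("continuous", "endpoints")) {
  rule <- match.arg(rule)
  nf <- nrow(assignment$layer_matrix)
  if (t0_index + lag > nf) stop("t0_index + lag exceeds the trajectory", call. = FALSE)
  m <- membership_matrix(assignment, layer)
  if (rule == "endpoints" || lag == 0) {
    m[t0_index, ] & m[t0_index + lag, ]
  } else {
    colSums(m[t0_index:(t0_index + lag), , drop = FALSE]) == lag + 1
  }
}

#' Export a layer assignment as tidy CSV
#' @param assignment A `layer_assignment`.
#' @param path Output path.
#' @export
write_layers_csv <- function(assignment, path) {
  utils::write.csv(assignment$table, path, row.names = FALSE)
  invisible(path)
}
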