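#' Construct an orthorhombic periodic box
#'
#' @param lengths Numeric vector of three edge lengths in Angstrom. A single
#'   value is recycled to a cubic box.
#' @return A numeric length-3 vector of class `aqua_box`.
#' @examples
#' make_box(70)            # cubic, 70 A
#' make_box(c(40, 50, 60)) # orthorhombic
#' @export
make_box <- function(lengths) {
  if (length(lengths) == 1) lengths <- rep(lengths, 3L)
  lengths <- as.numeric(lengths)
  if (length(lengths) != 3 || anyNA(lengths) || any(lengths <= 0)) {
    stop("box lengths must be three positive numbers (orthorhombic cells only)",
         call. = FALSE)
  }
  structure(lengths, class = "aqua_box")
}

#' Build a topology table
#'
#' A topology declares, per atom: element, mass (amu), partial charge (e),
#' molecule id and role. Roles are `"solute"`, `"water-O"`, `"water-H"` or
#' `"ion"`. Named solute groups (e.g. `"NH3"`, `"OH"`) are sets of atom ids
#' used for site-resolved selections.
#'
#' @param atoms Data frame with columns `id`, `element`, `mass`, `charge`,
#'   `mol_id`, `role`.
#' @param groups Named list of integer atom-id vectors.
#' @return A tibble of class `aqua_topology` with a `groups` attribute.
#' @export
make_topology <- function(atoms, groups = list()) {
  atoms <- tibble::as_tibble(atoms)
  needed <- c("id", "element", "mass", "charge", "mol_id", "role")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    stop("topology is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ok_roles <- c("solute", "water-O", "water-H", "ion")
  if (!all(atoms$role %in% ok_roles)) {
    stop("atom roles must be one of: ", paste(ok_roles, collapse = ", "),
         call. = FALSE)
  }
  # every water molecule must be exactly O + H + H
  wmol <- unique(atoms$mol_id[atoms$role %in% c("water-O", "water-H")])
  for (m in wmol) {
    r <- atoms$role[atoms$mol_id == m]
    if (!(sum(r == "water-O") == 1 && sum(r == "water-H") == 2 && length(r) == 3)) {
      stop("water molecule ", m, " is not exactly one O and two H", call. = FALSE)
    }
  }
  if (length(groups)) {
    bad <- !vapply(groups, function(g) all(g %in% atoms$id), logical(1))
    if (any(bad)) {
      stop("named groups reference unknown atom ids: ",
           paste(names(groups)[bad], collapse = ", "), call. = FALSE)
    }
  }
  structure(atoms, groups = groups, class = c("aqua_topology", class(atoms)))
}

#' @export
print.aqua_topology <- function(x, ...) {
  cat("<aqua_topology> ", nrow(x), " atoms; ",
      sum(x$role == "solute"), " solute, ",
      sum(x$role == "water-O"), " waters, ",
      sum(x$role == "ion"), " ions\n", sep = "")
  if (length(attr(x, "groups"))) {
    cat("groups:", paste(names(attr(x, "groups")), collapse = ", "), "\n")
  }
  NextMethod()
}

water_molecules <- function(topology) {
  sort(unique(topology$mol_id[topology$role == "water-O"]))
}

#' Construct a trajectory object
#'
#' Holds time-ordered frames of coordinates (Angstrom) with a periodic box and
#' a constant topology. Frame times (ps) must be strictly increasing with a
#' uniform step.
#'
#' @param coords Numeric array `n_frames x n_atoms x 3`, Angstrom.
#' @param times Numeric vector of frame times, ps.
#' @param box An `aqua_box`, or `NULL` for non-periodic (shape-only) analyses.
#' @param topology An `aqua_topology` whose atom count matches `dim(coords)[2]`,
#'   or `NULL`.
#' @param wrapped Logical; are coordinates wrapped into the box?
#' @param dt_tol Relative tolerance on timestep uniformity.
#' @return An object of class `aqua_trajectory`.
#' @export
make_trajectory <- function(coords, times, box = NULL, topology = NULL,
                            wrapped = TRUE, dt_tol = 1e-6) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("coords must be an n_frames x n_atoms x 3 array", call. = FALSE)
  }
  nf <- dim(coords)[1]
  if (length(times) != nf) stop("length(times) != n_frames", call. = FALSE)
  if (nf > 1) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("frame times must be strictly increasing", call. = FALSE)
    if (diff(range(dts)) > dt_tol * max(abs(dts))) {
      stop("non-uniform timestep: range ", min(dts), " .. ", max(dts), " ps",
           call. = FALSE)
    }
  }
  if (!is.null(topology) && nrow(topology) != dim(coords)[2]) {
    stop("coordinate count (", dim(coords)[2],
         ") does not match topology atom count (", nrow(topology), ")",
         call. = FALSE)
  }
  structure(list(coords = coords, times = as.numeric(times), box = box,
                 topology = topology, wrapped = wrapped),
            class = "aqua_trajectory")
}

#' @export
print.aqua_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("<aqua_trajectory> ", d[1], " frames x ", d[2], " atoms",
      if (d[1] > 1) paste0(", dt = ", signif(x$times[2] - x$times[1], 6), " ps"),
      if (!is.null(x$box)) paste0(", box = [", paste(signif(unclass(x$box), 6),
                                                     collapse = " "), "] A"),
      if (!x$wrapped) " (unwrapped)", "\n", sep = "")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
n_atoms <- function(traj) dim(traj$coords)[2]
traj_dt <- function(traj) if (n_frames(traj) > 1) traj$times[2] - traj$times[1] else NA_real_

#' Minimum-image displacement and distance
#'
#' `min_image_disp()` returns the displacement vector(s) `b - a` reduced to the
#' nearest periodic image; `minimum_image_distance()` its Euclidean norm. Both
#' accept single points or row-matched matrices of points.
#'
#' @param a,b Numeric length-3 vectors or `n x 3` matrices, Angstrom.
#' @param box An `aqua_box`.
#' @return Displacement matrix (`min_image_disp`) or distance vector.
#' @examples
#' b <- make_box(10)
#' minimum_image_distance(c(0, 0, 0), c(9, 0, 0), b) # 1
#' @export
min_image_disp <- function(a, b, box) {
  L <- unclass(box)
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  d <- b - a[rep_len(seq_len(nrow(a)), nrow(b)), , drop = FALSE]
  d - sweep(round(sweep(d, 2, L, "/")), 2, L, "*")
}

#' @rdname min_image_disp
#' @export
minimum_image_distance <- function(a, b, box) {
  d <- min_image_disp(a, b, box)
  sqrt(rowSums(d * d))
}

# All minimum-image distances from each row of `pts` (n x 3) to each row of
# `ref` (m x 3); returns an n x m matrix. Loop over the smaller ref set.
min_image_cross_dist <- function(pts, ref, box) {
  out <- matrix(0, nrow(pts), nrow(ref))
  for (j in seq_len(nrow(ref))) {
    out[, j] <- minimum_image_distance(ref[j, , drop = FALSE], pts, box)
  }
  out
}

#' Unwrap a trajectory across periodic boundaries
#'
#' Produces continuous coordinates by accumulating minimum-image inter-frame
#' displacements, so that mean-squared displacements are free of box-jump
#' artifacts. Requires the sampling to be fine enough that no atom moves half
#' a box length between consecutive frames.
#'
#' @param traj A wrapped `aqua_trajectory`.
#' @return The trajectory with continuous coordinates (`wrapped = FALSE`).
#' @export
unwrap_trajectory <- function(traj) {
  if (is.null(traj$box)) stop("cannot unwrap without a periodic box", call. = FALSE)
  L <- unclass(traj$box)
  co <- traj$coords
  nf <- dim(co)[1]
  if (nf > 1) {
    for (f in 2:nf) {
      d <- co[f, , , drop = FALSE] - co[f - 1, , , drop = FALSE]
      for (k in 1:3) {
        dk <- d[1, , k]
        shift <- round(dk / L[k])
        raw <- abs(dk - shift * L[k])
        if (any(raw >= L[k] / 2 - 1e-9)) {
          at <- which(raw >= L[k] / 2 - 1e-9)[1]
          stop("undersampled trajectory: atom ", at, " jumps ",
               signif(raw[at], 4), " A (>= L/2) between frames ", f - 1,
               " and ", f, call. = FALSE)
        }
        co[f, , k] <- co[f - 1, , k] + (dk - shift * L[k])
      }
    }
  }
  out <- traj
  out$coords <- co
  out$wrapped <- FALSE
  out
}

#' Wrap coordinates back into the primary box
#'
#' @param traj An `aqua_trajectory`.
#' @return The trajectory with all coordinates reduced to `[0, L)` per axis.
#' @export
wrap_trajectory <- function(traj) {
  if (is.null(traj$box)) stop("cannot wrap without a periodic box", call. = FALSE)
  L <- unclass(traj$box)
  co <- traj$coords
  for (k in 1:3) co[, , k] <- co[, , k] %% L[k]
  out <- traj
  out$coords <- co
  out$wrapped <- TRUE
  out
}

#' Per-frame water centres of mass
#'
#' Centres of mass use topology masses (not the geometric centre). Hydrogen
#' positions are taken in the oxygen's minimum image so wrapped molecules are
#' handled correctly.
#'
#' @param traj An `aqua_trajectory` with a water-bearing topology.
#' @return Array `n_frames x n_water x 3` of COM coordinates, plus water
#'   molecule ids as the `"mol_id"` attribute.
#' @export
water_com <- function(traj) {
  top <- traj$topology
  if (is.null(top)) stop("trajectory has no topology", call. = FALSE)
  wm <- water_molecules(top)
  nf <- n_frames(traj)
  out <- array(0, c(nf, length(wm), 3))
  # per molecule: indices of O and the two H
  h_idx <- lapply(wm, function(m) which(top$mol_id == m & top$role == "water-H"))
  oi <- vapply(wm, function(m) which(top$mol_id == m & top$role == "water-O"), integer(1))
  mO <- top$mass[oi]
  for (f in seq_len(nf)) {
    ro <- traj$coords[f, oi, , drop = TRUE]
    if (is.null(dim(ro))) ro <- matrix(ro, ncol = 3)
    acc <- ro * mO
    mt <- mO
    for (k in 1:2) {
      hi <- vapply(h_idx, `[`, integer(1), k)
      rh <- traj$coords[f, hi, , drop = TRUE]
      if (is.null(dim(rh))) rh <- matrix(rh, ncol = 3)
      if (!is.null(traj$box) && traj$wrapped) {
        rh <- ro + min_image_disp_rows(ro, rh, traj$box)
      }
      mh <- top$mass[hi]
      acc <- acc + rh * mh
      mt <- mt + mh
    }
    out[f, , ] <- acc / mt
  }
  attr(out, "mol_id") <- wm
  out
}

# row-wise minimum-image displacement b - a for equal-size matrices
min_image_disp_rows <- function(a, b, box) {
  L <- unclass(box)
  d <- b - a
  d - sweep(round(sweep(d, 2, L, "/")), 2, L, "*")
}
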