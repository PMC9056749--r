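#' Gyration tensor, radius and long axis
#'
#' The gyration tensor about the (mass-weighted) centroid; its eigenvalues in
#' descending order sum to the squared gyration radius, and the eigenvector of
#' the largest eigenvalue is the molecule's long axis.
#'
#' @param xyz `n x 3` coordinate matrix, Angstrom.
#' @param masses Atomic masses (recycled); ignored when
#'   `mass_weighted = FALSE`.
#' @param mass_weighted Weight by mass (default TRUE)?
#' @return A list: `Rg` (Angstrom), `eigenvalues` (descending, Angstrom^2),
#'   `long_axis` (unit 3-vector), `degenerate` flag (single-atom input).
#' @export
gyration <- function(xyz, masses = NULL, mass_weighted = TRUE) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  w <- if (mass_weighted && !is.null(masses)) rep_len(masses, n) else rep(1, n)
  w <- w / sum(w)
  c0 <- colSums(xyz * w)
  rc <- sweep(xyz, 2, c0)
  if (n < 2) {
    return(list(Rg = 0, eigenvalues = c(0, 0, 0), long_axis = c(NA, NA, NA),
                degenerate = TRUE))
  }
  S <- crossprod(rc * sqrt(w))  # sum_i w_i (r_i - c)(r_i - c)^T
  eg <- eigen(S, symmetric = TRUE)
  list(Rg = sqrt(sum(eg$values)), eigenvalues = eg$values,
       long_axis = eg$vectors[, 1], degenerate = FALSE)
}

#' Asphericity from gyration-tensor eigenvalues
#'
#' `b = lambda1 - (lambda2 + lambda3)/2` in Angstrom^2, zero for spherical
#' symmetry, along with the dimensionless `b / Rg^2` (1 for a rod, 1/4 for a
#' planar disc).
#'
#' @param eigenvalues Descending gyration-tensor eigenvalues, Angstrom^2.
#' @return Tibble: `b` (Angstrom^2), `b_normalized`.
#' @export
asphericity <- function(eigenvalues) {
  ev <- sort(as.numeric(eigenvalues), decreasing = TRUE)
  b <- ev[1] - (ev[2] + ev[3]) / 2
  rg2 <- sum(ev)
  tibble::tibble(b = b, b_normalized = if (rg2 > 0) b / rg2 else 0)
}

# Optimal proper-rotation (Kabsch) superposition of `mobile` onto `ref`.
# Returns the rotation applied to centred mobile coordinates; reflections
# are excluded.
kabsch <- function(mobile, ref, weights = NULL) {
  n <- nrow(mobile)
  w <- if (is.null(weights)) rep(1, n) else weights / sum(weights) * n
  cm <- colSums(mobile * w) / sum(w)
  cr <- colSums(ref * w) / sum(w)
  P <- sweep(mobile, 2, cm); Q <- sweep(ref, 2, cr)
  H <- crossprod(P * w, Q)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = R, centroid_mobile = cm, centroid_ref = cr)
}

#' RMSD of each frame to a reference conformation
#'
#' With superposition (default), each frame is optimally aligned to the
#' reference (proper rotation + translation, reflections excluded) before the
#' root-mean-square of atomic deviations; without, deviations are taken after
#' centroid removal only.
#'
#' @param traj An `aqua_trajectory`.
#' @param reference Reference frame index (default 1) or an `n x 3` matrix.
#' @param atoms Atom indices (default: solute atoms when a topology is
#'   present, else all).
#' @param superpose Optimal alignment first (default TRUE)?
#' @return Tibble: frame, time, rmsd (Angstrom).
#' @export
rmsd_to_reference <- function(traj, reference = 1, atoms = NULL,
                              superpose = TRUE) {
  if (is.null(atoms)) {
    atoms <- if (!is.null(traj$topology) && any(traj$topology$role == "solute")) {
      which(traj$topology$role == "solute")
    } else seq_len(n_atoms(traj))
  }
  ref <- if (is.matrix(reference)) reference
         else matrix(traj$coords[reference, atoms, ], ncol = 3)
  if (superpose && nrow(ref) < 3) {
    stop("superposition needs at least 3 atoms", call. = FALSE)
  }
  if (superpose) {
    sp <- ref[2:nrow(ref), ] - ref[rep(1, nrow(ref) - 1), ]
    if (qr(sp)$rank < 2) {
      stop("superposition is degenerate: reference atoms are collinear",
           call. = FALSE)
    }
  }
  nf <- n_frames(traj)
  out <- numeric(nf)
  ref_c <- sweep(ref, 2, colMeans(ref))
  for (f in seq_len(nf)) {
    x <- matrix(traj$coords[f, atoms, ], ncol = 3)
    xc <- sweep(x, 2, colMeans(x))
    if (superpose) {
      R <- kabsch(x, ref)$rotation
      xc <- xc %*% R
    }
    out[f] <- sqrt(mean(rowSums((xc - ref_c)^2)))
  }
  tibble::tibble(frame = seq_len(nf), time = traj$times, rmsd = out)
}

#' Per-frame solute shape descriptors
#'
#' Gyration radius, gyration-tensor eigenvalues, asphericity (raw and
#' normalized) and RMSD to the first frame, per trajectory frame.
#'
#' @param traj An `aqua_trajectory` with solute atoms (or give `atoms`).
#' @param atoms Atom indices (default: solute).
#' @param mass_weighted Mass-weighted gyration tensor (default TRUE)?
#' @param superpose Superpose before RMSD (default TRUE)?
#' @return A `shape_series` tibble: frame, time, Rg, lambda1..3, b,
#'   b_normalized, rmsd.
#' @export
shape_series <- function(traj, atoms = NULL, mass_weighted = TRUE,
                         superpose = TRUE) {
  if (is.null(atoms)) {
    atoms <- if (!is.null(traj$topology) && any(traj$topology$role == "solute")) {
      which(traj$topology$role == "solute")
    } else seq_len(n_atoms(traj))
  }
  masses <- if (!is.null(traj$topology)) traj$topology$mass[atoms] else NULL
  nf <- n_frames(traj)
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    g <- gyration(matrix(traj$coords[f, atoms, ], ncol = 3), masses,
                  mass_weighted)
    asp <- asphericity(g$eigenvalues)
    rows[[f]] <- tibble::tibble(frame = f, time = traj$times[f], Rg = g$Rg,
                                lambda1 = g$eigenvalues[1],
                                lambda2 = g$eigenvalues[2],
                                lambda3 = g$eigenvalues[3],
                                b = asp$b, b_normalized = asp$b_normalized)
  }
  out <- dplyr::bind_rows(rows)
  rms <- rmsd_to_reference(traj, atoms = atoms, superpose = superpose)
  out$rmsd <- rms$rmsd
  structure(out, class = c("shape_series", class(out)))
}
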