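#' Read a trajectory from a standard MD file
#'
#' Supported formats: extended XYZ (`"xyz"`, box lengths `Lx Ly Lz` on the
#' comment line), DL_POLY `HISTORY` (`"dlpoly-history"`, levcfg 0-2;
#' velocities and forces are skipped with a message) and PDB
#' (`"pdb"`, single- or multi-MODEL; mainly useful to bootstrap a topology).
#' Coordinates are returned in Angstrom and times in ps.
#'
#' @param path File path.
#' @param format One of `"xyz"`, `"dlpoly-history"`, `"pdb"`; `"auto"` sniffs
#'   from the file header.
#' @param topology Optional `aqua_topology`; atom counts are checked against it.
#' @param dt Frame interval in ps used when the file carries no time metadata
#'   (XYZ, PDB). Default 1 ps.
#' @return An `aqua_trajectory`.
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "dlpoly-history", "pdb"),
                            topology = NULL, dt = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- sniff_format(path)
  traj <- switch(format,
    "xyz" = read_xyz(path, topology = topology, dt = dt),
    "dlpoly-history" = read_dlpoly_history(path, topology = topology),
    "pdb" = read_pdb_trajectory(path, topology = topology, dt = dt)
  )
  traj
}

sniff_format <- function(path) {
  head <- readLines(path, n = 4L, warn = FALSE)
  if (length(head) >= 1 && grepl("^\\s*\\d+\\s*$", head[1])) return("xyz")
  if (length(head) >= 2 && grepl("^\\s*\\d+\\s+\\d+", head[2]) &&
      !grepl("^\\s*\\d+\\s*$", head[1])) return("dlpoly-history")
  if (any(grepl("^(ATOM|HETATM|MODEL|HEADER|CRYST1)", head))) return("pdb")
  stop("cannot determine trajectory format of ", path, call. = FALSE)
}

#' Read an (extended) XYZ trajectory
#'
#' The comment line of each frame may carry the orthorhombic box lengths as
#' three numbers `Lx Ly Lz`; absence of box metadata yields a box-free
#' trajectory usable only for non-periodic (shape) analyses.
#'
#' @inheritParams read_trajectory
#' @export
read_xyz <- function(path, topology = NULL, dt = 1) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  frames <- list()
  boxes <- list()
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed XYZ: expected atom count at line ", i, call. = FALSE)
    if (i + 1L + nat > length(lines)) {
      stop("malformed XYZ: truncated frame starting at line ", i, call. = FALSE)
    }
    comment <- lines[i + 1L]
    nums <- suppressWarnings(as.numeric(strsplit(trimws(comment), "\\s+")[[1]]))
    boxes[[length(boxes) + 1L]] <-
      if (length(nums) >= 3 && !anyNA(nums[1:3])) nums[1:3] else NULL
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    el <- vapply(toks, `[`, character(1), 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nat
  }
  nf <- length(frames)
  na <- nrow(frames[[1]])
  if (!is.null(topology) && nrow(topology) != na) {
    stop("XYZ atom count (", na, ") does not match topology (",
         nrow(topology), ")", call. = FALSE)
  }
  co <- array(0, c(nf, na, 3))
  for (f in seq_len(nf)) co[f, , ] <- frames[[f]]
  box <- if (!is.null(boxes[[1]])) make_box(boxes[[1]]) else NULL
  traj <- make_trajectory(co, times = dt * (seq_len(nf) - 1), box = box,
                          topology = topology)
  attr(traj, "elements") <- elements
  traj
}

#' Write a trajectory as extended XYZ
#'
#' Box lengths, when present, are written on each frame's comment line as
#' `Lx Ly Lz`.
#'
#' @param traj An `aqua_trajectory`.
#' @param path Output path.
#' @param elements Optional character vector of element symbols; defaults to
#'   the topology's, or `"X"`.
#' @param digits Number of decimal places for coordinates (default 8).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, elements = NULL, digits = 8) {
  na <- n_atoms(traj)
  if (is.null(elements)) {
    elements <- if (!is.null(traj$topology)) traj$topology$element else rep("X", na)
  }
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(na), con)
    writeLines(if (!is.null(traj$box))
      paste(sprintf("%.6f", unclass(traj$box)), collapse = " ") else "", con)
    xyz <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf(fmt, elements, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a DL_POLY HISTORY trajectory
#'
#' Handles levcfg 0 (coordinates), 1 (+velocities) and 2 (+forces); only
#' coordinates are used, and the presence of skipped velocity/force records is
#' reported once via `message()`. Only orthorhombic cells are accepted. Times
#' are reconstructed from `timestep` records (step index times the integration
#' step).
#'
#' @inheritParams read_trajectory
#' @export
read_dlpoly_history <- function(path, topology = NULL) {
  lines <- readLines(path, warn = FALSE)
  # skip header: title line + "levcfg imcon natms [...]" line
  info <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  levcfg <- info[1]
  imcon <- info[2]
  if (!imcon %in% c(0, 1, 2)) {
    stop("only orthorhombic (imcon 1/2) or non-periodic cells are supported; imcon = ",
         imcon, call. = FALSE)
  }
  if (levcfg >= 1) message("HISTORY contains velocities",
                           if (levcfg >= 2) " and forces",
                           "; skipped (coordinates only)")
  per_atom <- 2L + levcfg  # name line + coord line (+ vel, + force)
  i <- 3L
  frames <- list(); times <- numeric(); boxes <- list(); elements <- NULL
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (toupper(tok[1]) != "TIMESTEP") stop("malformed HISTORY at line ", i, call. = FALSE)
    nstep <- as.numeric(tok[2]); natms <- as.integer(tok[3])
    tstep <- as.numeric(tok[6])
    times <- c(times, nstep * tstep)
    cell <- t(vapply(lines[(i + 1):(i + 3)],
                     function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                     numeric(3)))
    off <- abs(cell[row(cell) != col(cell)])
    if (imcon != 0 && any(off > 1e-8)) {
      stop("triclinic HISTORY cell not supported", call. = FALSE)
    }
    boxes[[length(boxes) + 1L]] <- diag(cell)
    j <- i + 4L
    xyz <- matrix(0, natms, 3)
    el <- character(natms)
    for (a in seq_len(natms)) {
      el[a] <- strsplit(trimws(lines[j]), "\\s+")[[1]][1]
      xyz[a, ] <- as.numeric(strsplit(trimws(lines[j + 1]), "\\s+")[[1]])[1:3]
      j <- j + per_atom
    }
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    i <- j
  }
  nf <- length(frames)
  na <- nrow(frames[[1]])
  if (!is.null(topology) && nrow(topology) != na) {
    stop("HISTORY atom count (", na, ") does not match topology (",
         nrow(topology), ")", call. = FALSE)
  }
  co <- array(0, c(nf, na, 3))
  for (f in seq_len(nf)) co[f, , ] <- frames[[f]]
  box <- if (imcon != 0) make_box(boxes[[1]]) else NULL
  # DL_POLY cells are centred at the origin; shift into [0, L)
  if (!is.null(box)) for (k in 1:3) co[, , k] <- co[, , k] %% unclass(box)[k]
  traj <- make_trajectory(co, times = times, box = box, topology = topology)
  attr(traj, "elements") <- elements
  traj
}

read_pdb_trajectory <- function(path, topology = NULL, dt = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  co3 <- pdb$xyz
  nf <- nrow(co3)
  na <- ncol(co3) / 3
  co <- array(0, c(nf, na, 3))
  for (f in seq_len(nf)) co[f, , ] <- matrix(co3[f, ], ncol = 3, byrow = TRUE)
  if (!is.null(topology) && nrow(topology) != na) {
    stop("PDB atom count (", na, ") does not match topology (",
         nrow(topology), ")", call. = FALSE)
  }
  make_trajectory(co, times = dt * (seq_len(nf) - 1), box = NULL,
                  topology = topology)
}

#' Bootstrap a topology from a PDB file
#'
#' Waters (residue names HOH/WAT/TIP/SOL/SPC) are assigned `water-O` /
#' `water-H` roles; everything else becomes `solute`. Masses come from a small
#' element table; charges default to 0 and can be overwritten afterwards.
#'
#' @param path PDB file path.
#' @return An `aqua_topology`.
#' @export
read_topology_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  el <- at$elesy
  if (all(!nzchar(trimws(el)))) el <- substr(trimws(at$elety), 1, 1)
  el <- trimws(el)
  water_res <- c("HOH", "WAT", "TIP", "TIP3", "TIP4", "SOL", "SPC")
  is_w <- at$resid %in% water_res
  role <- ifelse(is_w & el == "O", "water-O",
          ifelse(is_w & el == "H", "water-H", "solute"))
  mol <- cumsum(!duplicated(paste(at$resno, at$chain)))
  make_topology(tibble::tibble(
    id = seq_len(nrow(at)),
    element = el,
    mass = element_mass(el),
    charge = 0,
    mol_id = mol,
    role = role
  ))
}

element_mass <- function(el) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, Na = 22.990, Cl = 35.45, X = 1)
  m <- tab[el]
  m[is.na(m)] <- 1
  unname(m)
}

#' Convenience topology for pure-water (plus optional solute) systems
#'
#' Builds an `aqua_topology` with `n_solute` leading solute atoms followed by
#' `n_water` three-site waters (O, H, H in order). Water charges default to a
#' rigid three-site model (O -0.8476 e, H +0.4238 e) so dipoles are defined.
#'
#' @param n_water Number of water molecules.
#' @param n_solute Number of solute atoms prepended (mass 12, charge 0).
#' @param groups Optional named list of solute atom-id sets.
#' @return An `aqua_topology`.
#' @export
water_system_topology <- function(n_water, n_solute = 0, groups = list()) {
  sol <- if (n_solute > 0) {
    tibble::tibble(id = seq_len(n_solute), element = "C", mass = 12.011,
                   charge = 0, mol_id = seq_len(n_solute), role = "solute")
  } else NULL
  wid0 <- n_solute
  wat <- tibble::tibble(
    id = wid0 + seq_len(3 * n_water),
    element = rep(c("O", "H", "H"), n_water),
    mass = rep(c(15.999, 1.008, 1.008), n_water),
    charge = rep(c(-0.8476, 0.4238, 0.4238), n_water),
    mol_id = n_solute + rep(seq_len(n_water), each = 3),
    role = rep(c("water-O", "water-H", "water-H"), n_water)
  )
  make_topology(dplyr::bind_rows(sol, wat), groups = groups)
}
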