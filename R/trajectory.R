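#' Construct a trajectory
#'
#' Frames of Cartesian coordinates for the atoms of a topology, with a
#' per-frame orthorhombic box. All lengths are in nanometres internally;
#' readers convert from Angstrom where the format demands it.
#'
#' @param coords Numeric array `[n_frames, n_atoms, 3]` in nm.
#' @param box Per-frame box edge lengths: an `n_frames x 3` matrix or a
#'   length-3 vector recycled to all frames (nm).
#' @param times Frame times in ps; defaults to `0:(n_frames-1)`.
#' @return An object of class `ln_traj`.
#' @export
trajectory <- function(coords, box, times = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  nf <- dim(coords)[1]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  box <- as.matrix(box)
  stopifnot(nrow(box) == nf, ncol(box) == 3, all(box > 0))
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1)
  stopifnot(length(times) == nf)
  structure(list(coords = coords, box = box, times = as.numeric(times)),
            class = "ln_traj")
}

#' @export
print.ln_traj <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[1], "frames x", dim(x$coords)[2],
      "atoms; box", paste(signif(x$box[1, ], 4), collapse = " x "), "nm\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
n_atoms <- function(traj) dim(traj$coords)[2]

check_traj_topology <- function(traj, top) {
  if (n_atoms(traj) != nrow(top)) {
    stop("trajectory has ", n_atoms(traj), " atoms but topology has ",
         nrow(top))
  }
  invisible(TRUE)
}

# Minimum-image distances from one reference atom to a set of target atoms,
# for every frame. Returns an n_frames x n_targets matrix (nm). Orthorhombic
# boxes only; cutoffs used downstream must stay below half the smallest edge.
atom_set_distances <- function(traj, ref, targets) {
  nf <- n_frames(traj)
  nt <- length(targets)
  if (nt == 0) return(matrix(numeric(0), nrow = nf, ncol = 0))
  d2 <- matrix(0, nf, nt)
  for (k in 1:3) {
    dx <- traj$coords[, targets, k, drop = TRUE] - traj$coords[, ref, k]
    dx <- matrix(dx, nf, nt)
    bk <- traj$box[, k]
    dx <- dx - bk * round(dx / bk)
    d2 <- d2 + dx * dx
  }
  sqrt(d2)
}

# Per-frame minimum-image distance between two single atoms.
atom_pair_distance <- function(traj, i, j) {
  as.numeric(atom_set_distances(traj, i, j))
}
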