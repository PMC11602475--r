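## Coordinate containers.  Units: nm and ps throughout; boxes orthorhombic.

#' Construct a single coordinate frame
#'
#' @param coords N x 3 numeric matrix of coordinates (nm).
#' @param box length-3 numeric, orthorhombic box edges (nm).
#' @param time frame time (ps).
#' @param atoms optional per-atom metadata data.frame (see [make_atoms()]).
#' @return An object of class `md_frame`.
#' @export
md_frame <- function(coords, box, time = 0, atoms = NULL) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  if (ncol(coords) != 3L) ox_stop("coords must be an N x 3 matrix")
  if (!all(is.finite(coords))) ox_stop("coordinates must be finite")
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    ox_stop("box must be 3 strictly positive lengths (orthorhombic)")
  }
  if (!is.null(atoms) && nrow(atoms) != nrow(coords)) {
    ox_stop("atoms metadata rows (", nrow(atoms),
            ") do not match coordinate rows (", nrow(coords), ")")
  }
  structure(list(coords = coords, box = box, time = as.numeric(time),
                 atoms = atoms),
            class = "md_frame")
}

#' Construct per-atom metadata
#'
#' @param resid integer residue ids.
#' @param resname residue (species) names.
#' @param name atom names.
#' @param mass atomic masses (amu), must be > 0.
#' @param species species code per atom (defaults to `resname`).
#' @param leaflet leaflet tag (`"inner"`, `"outer"` or `NA`).
#' @return data.frame with those columns.
#' @export
make_atoms <- function(resid, resname, name, mass,
                       species = resname, leaflet = NA_character_) {
  n <- length(resid)
  if (any(mass <= 0)) ox_stop("atom masses must be > 0")
  data.frame(resid = as.integer(resid), resname = resname, name = name,
             mass = as.numeric(mass), species = species,
             leaflet = rep_len(leaflet, n), stringsAsFactors = FALSE)
}

#' Construct a trajectory
#'
#' @param atoms per-atom metadata ([make_atoms()]).
#' @param coords either an N x 3 x T array or a list of T N x 3 matrices (nm).
#' @param times length-T numeric frame times (ps), strictly increasing.
#' @param box either a length-3 vector (constant box) or a T x 3 matrix (nm).
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(atoms, coords, times, box) {
  if (is.list(coords)) {
    n <- nrow(coords[[1]])
    if (any(vapply(coords, nrow, 0L) != n)) {
      ox_stop("atom count must be constant across frames")
    }
    arr <- array(0, dim = c(n, 3L, length(coords)))
    for (i in seq_along(coords)) arr[, , i] <- coords[[i]]
    coords <- arr
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  nt <- dim(coords)[3]
  if (nt == 0L) ox_stop("trajectory has no frames")
  times <- as.numeric(times)
  if (length(times) != nt) ox_stop("times length must equal frame count")
  if (nt > 1L && any(diff(times) <= 0)) ox_stop("frame times must be strictly increasing")
  if (is.null(dim(box))) box <- matrix(box, nrow = nt, ncol = 3L, byrow = TRUE)
  if (nrow(box) != nt || ncol(box) != 3L) ox_stop("box must be T x 3")
  if (any(box <= 0)) ox_stop("box lengths must be > 0")
  if (nrow(atoms) != dim(coords)[1]) {
    ox_stop("atoms metadata rows (", nrow(atoms),
            ") do not match coordinate rows (", dim(coords)[1], ")")
  }
  if (any(atoms$mass <= 0)) ox_stop("atom masses must be > 0")
  structure(list(atoms = atoms, coords = coords, times = times, box = box),
            class = "md_trajectory")
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame from a trajectory
#' @param traj an `md_trajectory`.
#' @param i frame index.
#' @return An `md_frame` carrying the trajectory's atom metadata.
#' @export
traj_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  md_frame(traj$coords[, , i], traj$box[i, ], traj$times[i], traj$atoms)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d atoms x %d frames, t = %g..%g ps\n",
              dim(x$coords)[1], n_frames(x), x$times[1],
              x$times[n_frames(x)]))
  invisible(x)
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("md_frame: %d atoms, box %.3f x %.3f x %.3f nm, t = %g ps\n",
              nrow(x$coords), x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

## Wrap coordinates into [0, box) per axis (orthorhombic).
wrap_coords <- function(coords, box) {
  for (k in 1:3) coords[, k] <- coords[, k] %% box[k]
  coords
}
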