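## Minimal CHARMM-style DCD trajectory codec (binary, Fortran sequential
## records).  Written because no installed R package provides a DCD *writer*;
## the reader is cross-checked against bio3d::read.dcd in the test suite.
## Coordinates on disk are in angstroms (DCD convention); the API speaks nm.
## The header's delta slot stores the frame spacing in ps, so times survive a
## round trip.  XTC (XDR-compressed) trajectories are not supported; request
## for format "XTC" raises an explicit error.

write_record <- function(con, raw_payload) {
  writeBin(as.integer(length(raw_payload)), con, size = 4L)
  writeBin(raw_payload, con)
  writeBin(as.integer(length(raw_payload)), con, size = 4L)
}

raw_int <- function(x) writeBin(as.integer(x), raw(), size = 4L)
raw_float <- function(x) writeBin(as.numeric(x), raw(), size = 4L)
raw_double <- function(x) writeBin(as.numeric(x), raw(), size = 8L)

#' Write a trajectory as a DCD file
#'
#' @param traj an `md_trajectory`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  natom <- dim(traj$coords)[1]
  dt <- if (nf > 1L) traj$times[2] - traj$times[1] else 1
  t0 <- traj$times[1]
  con <- file(path, "wb")
  on.exit(close(con))
  icntrl <- integer(20)
  icntrl[1] <- nf           # number of frames
  icntrl[2] <- round(t0 / dt)  # first timestep index
  icntrl[3] <- 1L           # steps between frames
  icntrl[11] <- 1L          # unit-cell records present
  icntrl[20] <- 24L         # CHARMM version stamp
  hdr <- c(charToRaw("CORD"),
           raw_int(icntrl[1:9]),
           raw_float(dt),          # delta, stored as float32 (ps)
           raw_int(icntrl[11:20]))
  write_record(con, hdr)
  title <- sprintf("%-80s", "oxbilayer DCD; delta in ps")
  write_record(con, c(raw_int(1L), charToRaw(title)))
  write_record(con, raw_int(natom))
  for (i in seq_len(nf)) {
    b <- traj$box[i, ] * 10  # nm -> A
    write_record(con, raw_double(c(b[1], 0, b[2], 0, 0, b[3])))
    xyz <- traj$coords[, , i] * 10
    write_record(con, raw_float(xyz[, 1]))
    write_record(con, raw_float(xyz[, 2]))
    write_record(con, raw_float(xyz[, 3]))
  }
  invisible(path)
}

read_record <- function(con, what, size, endian) {
  nbytes <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (length(nbytes) == 0L) return(NULL)
  n <- nbytes / size
  payload <- readBin(con, what, n, size = size, endian = endian)
  tail <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (length(tail) == 0L || tail != nbytes) ox_stop("corrupt DCD record")
  payload
}

#' Read a topology + DCD trajectory pair
#'
#' @param topology path to a GRO or PDB coordinate file supplying atom
#'   metadata and count.
#' @param trajectory path to the DCD file.
#' @param format trajectory format; only `"DCD"` is supported (`"XTC"` raises
#'   an informative error).
#' @return An `md_trajectory`; frame times are reconstructed from the DCD
#'   header (first step, step interval, delta).
#' @export
read_trajectory <- function(topology, trajectory, format = "DCD") {
  format <- toupper(format)
  if (format == "XTC") {
    ox_stop("XTC trajectories are not supported; use DCD")
  }
  if (format != "DCD") ox_stop("unsupported trajectory format: ", format)
  top <- read_coordinates(topology)
  con <- file(trajectory, "rb")
  on.exit(close(con))
  ## endianness probe: first record marker must be 84
  probe <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- if (identical(probe, 84L)) "little" else "big"
  seek(con, 0L)
  hdr <- readBin(con, "raw", 4L + 84L + 4L)
  if (length(hdr) < 92L || rawToChar(hdr[5:8]) != "CORD") {
    ox_stop("not a DCD file: ", trajectory)
  }
  ints <- readBin(hdr[9:92], "integer", 20L, size = 4L, endian = endian)
  nf <- ints[1]; istart <- ints[2]; interval <- max(1L, ints[3])
  delta <- readBin(hdr[9:92][37:40], "numeric", 1L, size = 4L, endian = endian)
  has_cell <- ints[11] == 1L
  invisible(read_record(con, "raw", 1L, endian))     # title block
  natom <- read_record(con, "integer", 4L, endian)
  if (length(natom) != 1L) ox_stop("corrupt DCD natom record")
  if (natom != nrow(top$coords)) {
    ox_stop("atom-count mismatch: topology has ", nrow(top$coords),
            " atoms, trajectory has ", natom)
  }
  if (nf < 1L) ox_stop("empty trajectory: ", trajectory)
  coords <- array(0, dim = c(natom, 3L, nf))
  box <- matrix(0, nf, 3L)
  for (i in seq_len(nf)) {
    if (has_cell) {
      cell <- read_record(con, "numeric", 8L, endian)
      if (is.null(cell)) ox_stop("DCD truncated at frame ", i)
      if (any(abs(cell[c(2, 4, 5)]) > 1e-6)) {
        ox_stop("triclinic boxes are not supported (DCD frame ", i, ")")
      }
      box[i, ] <- cell[c(1, 3, 6)] / 10
    } else {
      box[i, ] <- top$box
    }
    x <- read_record(con, "numeric", 4L, endian)
    y <- read_record(con, "numeric", 4L, endian)
    z <- read_record(con, "numeric", 4L, endian)
    if (is.null(x) || is.null(y) || is.null(z)) {
      ox_stop("DCD truncated at frame ", i)
    }
    coords[, , i] <- cbind(x, y, z) / 10
  }
  times <- (istart + (seq_len(nf) - 1L) * interval) * delta
  md_trajectory(top$atoms, coords, times, box)
}
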