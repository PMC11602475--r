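## Coordinate file I/O.  GRO is parsed/written directly (fixed-width, nm
## native); PDB goes through bio3d with an A -> nm conversion on ingest.
## Boxes must be orthorhombic; triclinic input is rejected explicitly.

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06)

## Guess element and mass from an atom name ("P8", "C21", "OW", "H12", ...).
guess_masses <- function(names) {
  el <- sub("^[0-9]*", "", names)
  el <- substr(el, 1L, 1L)
  m <- .element_masses[el]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Read a coordinate file (GRO or PDB)
#'
#' Coordinates are returned in nm regardless of the source units (PDB
#' angstroms are converted). Atom naming is preserved verbatim; masses are
#' inferred from the element implied by the atom name.
#'
#' @param path file path.
#' @param format `"GRO"` or `"PDB"`; default guessed from the extension.
#' @return An `md_frame` with populated `atoms` metadata.
#' @export
read_coordinates <- function(path, format = NULL) {
  format <- toupper(format %||% tools::file_ext(path))
  fr <- switch(format,
               GRO = read_gro(path),
               PDB = read_pdb_frame(path),
               ox_stop("unsupported coordinate format: ", format))
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (length(meta$species) == nrow(fr$atoms)) {
      fr$atoms$species <- meta$species
      fr$atoms$leaflet <- meta$leaflet
      fr$atoms$resname <- meta$resname
    }
  }
  fr
}

read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) ox_stop("GRO file truncated at line ", length(lines),
                                  ": ", path)
  natom <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natom)) ox_stop("GRO parse error at line 2: atom count not an integer")
  if (length(lines) < 2L + natom + 1L) {
    ox_stop("GRO file truncated at line ", length(lines),
            ": expected ", 2L + natom + 1L, " lines")
  }
  time <- 0
  if (grepl("t=", lines[1])) {
    time <- suppressWarnings(as.numeric(sub(".*t=\\s*([-0-9.eE+]+).*", "\\1", lines[1])))
    if (is.na(time)) time <- 0
  }
  al <- lines[3:(2L + natom)]
  resid <- suppressWarnings(as.integer(substr(al, 1L, 5L)))
  resname <- trimws(substr(al, 6L, 10L))
  aname <- trimws(substr(al, 11L, 15L))
  x <- suppressWarnings(as.numeric(substr(al, 21L, 28L)))
  y <- suppressWarnings(as.numeric(substr(al, 29L, 36L)))
  z <- suppressWarnings(as.numeric(substr(al, 37L, 44L)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) ox_stop("GRO parse error at line ", 2L + bad[1], ": malformed atom record")
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[2L + natom + 1L]),
                                               "\\s+")[[1]]))
  if (length(boxv) < 3L || any(is.na(boxv[1:3]))) {
    ox_stop("GRO parse error at line ", 2L + natom + 1L, ": malformed box record")
  }
  if (length(boxv) > 3L && any(abs(boxv[-(1:3)]) > 1e-9)) {
    ox_stop("triclinic boxes are not supported (off-diagonal box elements present)")
  }
  atoms <- make_atoms(resid, resname, aname, guess_masses(aname))
  md_frame(cbind(x, y, z), boxv[1:3], time, atoms)
}

read_pdb_frame <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) ox_stop("PDB parse error in ", path, ": ",
                                              conditionMessage(e)))
  xyz <- matrix(pdb$xyz[1, ], ncol = 3L, byrow = TRUE) / 10  # A -> nm
  a <- pdb$atom
  box <- c(10, 10, 10)
  cr <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cr)) {
    abc <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                                         substr(cr[1], 25, 33))))
    ang <- suppressWarnings(as.numeric(c(substr(cr[1], 34, 40), substr(cr[1], 41, 47),
                                         substr(cr[1], 48, 54))))
    if (!any(is.na(abc))) box <- abc / 10
    if (!any(is.na(ang)) && any(abs(ang - 90) > 1e-6)) {
      ox_stop("triclinic boxes are not supported (CRYST1 angles != 90)")
    }
  }
  atoms <- make_atoms(a$resno, a$resid, a$elety, guess_masses(a$elety))
  md_frame(xyz, box, 0, atoms)
}

#' Write a coordinate frame (GRO or PDB)
#'
#' @param frame an `md_frame` with `atoms` metadata.
#' @param path output path.
#' @param format `"GRO"` or `"PDB"`; default guessed from the extension.
#' @return Invisibly, `path`.
#' @export
write_coordinates <- function(frame, path, format = NULL) {
  stopifnot(inherits(frame, "md_frame"))
  if (is.null(frame$atoms)) ox_stop("frame has no atom metadata to write")
  format <- toupper(format %||% tools::file_ext(path))
  switch(format,
         GRO = write_gro(frame, path),
         PDB = write_pdb_frame(frame, path),
         ox_stop("unsupported coordinate format: ", format))
  ## species codes and leaflet tags exceed what GRO/PDB name columns hold;
  ## they ride along in a JSON sidecar and are merged back on read
  jsonlite::write_json(list(species = frame$atoms$species,
                            leaflet = frame$atoms$leaflet,
                            resname = frame$atoms$resname),
                       paste0(path, ".meta.json"), digits = NA, null = "null")
  invisible(path)
}

write_gro <- function(frame, path) {
  a <- frame$atoms
  n <- nrow(frame$coords)
  lines <- character(n + 3L)
  lines[1] <- sprintf("frame t= %.3f", frame$time)
  lines[2] <- sprintf("%5d", n)
  lines[3:(n + 2L)] <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                               a$resid %% 100000L, substr(a$resname, 1, 5),
                               substr(a$name, 1, 5), seq_len(n) %% 100000L,
                               frame$coords[, 1], frame$coords[, 2],
                               frame$coords[, 3])
  lines[n + 3L] <- sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                           frame$box[3])
  writeLines(lines, path)
}

write_pdb_frame <- function(frame, path) {
  a <- frame$atoms
  xyz <- as.vector(t(frame$coords * 10))  # nm -> A
  ## PDB resname columns hold 3 characters; longer species codes are
  ## truncated on disk and preserved through the metadata sidecar
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resid,
                   resid = substr(a$resname, 1, 3),
                   elety = substr(a$name, 1, 4))
  ## prepend a CRYST1 record so the box round-trips
  body <- readLines(path, warn = FALSE)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   frame$box[1] * 10, frame$box[2] * 10, frame$box[3] * 10,
                   90, 90, 90)
  writeLines(c(cryst, body), path)
}
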