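## Marker-resolution coordinate placement for a composition: one jittered
## lattice site per lipid per leaflet, with a small vertical stack of marker
## atoms (phosphate / cholesterol O3, carbonyl, mid-chain carbon, terminal
## methyl).  This is a toy placer for generating valid, collision-free input
## files; atomic packing is a packing engine's job and out of scope.

#' Place toy marker coordinates for a composition
#'
#' Each lipid gets marker atoms stacked along z at its leaflet's depth, on a
#' jittered square lattice. All inter-marker distances respect the packing
#' tolerance (the classic 2 A assembly tolerance = 0.2 nm by default);
#' placement is retried with fresh jitter a bounded number of times before
#' an infeasible-packing error.
#'
#' @param comp a `membrane_composition`.
#' @param box length-3 box (nm); must be wide enough for the counts at the
#'   tolerance.
#' @param tolerance minimum inter-marker distance (nm), default 0.2.
#' @param half_thickness leaflet phosphate depth from the membrane center
#'   (nm).
#' @param seed integer seed; identical seeds give identical coordinates.
#' @param max_retries jitter retries before giving up.
#' @return An `md_frame`; atoms carry `resid` (lipid index), `resname`
#'   (species), `leaflet` tags.
#' @export
place_toy_coordinates <- function(comp, box, tolerance = 0.2,
                                  half_thickness = 2.0, seed = 1L,
                                  max_retries = 20L) {
  stopifnot(inherits(comp, "membrane_composition"), tolerance > 0)
  tab <- comp$table
  lip <- tab[rep(seq_len(nrow(tab)), tab$count), c("leaflet", "species")]
  zc <- box[3] / 2
  marker_stack <- function(species, sgn) {
    if (species == "CHOL") {
      data.frame(name = "O3", mass = 15.999, z = sgn * (half_thickness - 0.8))
    } else {
      data.frame(name = c("P", "C1", "C8", "C16"),
                 mass = c(30.974, 12.011, 12.011, 12.011),
                 z = sgn * c(half_thickness, half_thickness - 0.6,
                             half_thickness - 1.2, 0.35))
    }
  }
  place_leaflet <- function(rows, sgn) {
    n <- nrow(rows)
    grid_n <- ceiling(sqrt(n))
    spacing <- min(box[1], box[2]) / grid_n
    if (spacing < tolerance) {
      ox_stop("infeasible packing: ", n, " lipids need spacing >= ", tolerance,
              " nm in a ", box[1], " x ", box[2], " nm leaflet")
    }
    jitter <- max(0, (spacing - tolerance) / 2 * 0.8)
    sites <- cbind(((seq_len(n) - 1L) %% grid_n + 0.5) * spacing,
                   ((seq_len(n) - 1L) %/% grid_n + 0.5) * spacing)
    for (attempt in seq_len(max_retries)) {
      xy <- sites + matrix(stats::runif(2 * n, -jitter, jitter), n, 2)
      d <- as.matrix(stats::dist(xy))
      diag(d) <- Inf
      if (min(d) >= tolerance) {
        return(xy)
      }
      jitter <- jitter * 0.6
    }
    ox_stop("infeasible packing after ", max_retries, " retries")
  }
  frame <- with_seed(seed, {
    out <- list()
    for (lf in c("inner", "outer")) {
      rows <- lip[lip$leaflet == lf, , drop = FALSE]
      if (!nrow(rows)) next
      sgn <- if (lf == "outer") 1 else -1
      xy <- place_leaflet(rows, sgn)
      for (i in seq_len(nrow(rows))) {
        st <- marker_stack(rows$species[i], sgn)
        out[[length(out) + 1L]] <- data.frame(
          leaflet = lf, species = rows$species[i],
          name = st$name, mass = st$mass,
          x = xy[i, 1], y = xy[i, 2], z = zc + st$z,
          lipid_in_leaflet = i)
      }
    }
    do.call(rbind, out)
  })
  frame$resid <- cumsum(!duplicated(paste(frame$leaflet, frame$lipid_in_leaflet)))
  atoms <- make_atoms(frame$resid, frame$species, frame$name, frame$mass,
                      leaflet = frame$leaflet)
  fr <- md_frame(as.matrix(frame[, c("x", "y", "z")]), box, 0, atoms)
  ## global tolerance audit (cross-leaflet distances are >> tolerance by
  ## construction, but verify the invariant outright)
  d <- as.matrix(stats::dist(fr$coords))
  diag(d) <- Inf
  if (min(d) < tolerance) ox_stop("infeasible packing: marker clash at ",
                                  format(min(d), digits = 3), " nm")
  fr
}
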