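## Mass-density profiles along the bilayer normal, water-zone occupancy,
## phosphate-peak thickness, area per lipid, and peak-shift comparisons.
## Profiles are recentered on the membrane center of mass frame by frame
## (center convention: membrane COM at z = 0).

#' Atom selection helper
#'
#' @param traj an `md_trajectory` or `md_frame`.
#' @param resname,name,species,leaflet optional filters; atoms matching all
#'   given filters are selected.
#' @return Integer atom indices.
#' @export
select_atoms <- function(traj, resname = NULL, name = NULL, species = NULL,
                         leaflet = NULL) {
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(species)) keep <- keep & a$species %in% species
  if (!is.null(leaflet)) keep <- keep & a$leaflet %in% leaflet
  which(keep)
}

membrane_center_indices <- function(traj) {
  idx <- which(traj$atoms$resname != "SOL")
  if (!length(idx)) seq_len(nrow(traj$atoms)) else idx
}

#' Mass density profile along the bilayer normal
#'
#' Per-frame mass histograms along z, recentered on the membrane center of
#' mass, converted to kg/m^3 and averaged over frames.
#'
#' @param traj an `md_trajectory`.
#' @param selections named list of atom index vectors, one per component.
#' @param bin_width histogram bin width (nm), default 0.05.
#' @param center_selection atoms defining the membrane COM; defaults to all
#'   non-water atoms.
#' @return A `density_profile`: list with `bin_centers` (nm), `density`
#'   (bins x components matrix, kg/m^3), `bin_width`, `components`,
#'   `n_frames`, `box_area` (mean lateral area, nm^2).
#' @export
mass_density_profile <- function(traj, selections, bin_width = 0.05,
                                 center_selection = NULL) {
  stopifnot(inherits(traj, "md_trajectory"), bin_width > 0)
  if (is.null(names(selections)) || any(!nzchar(names(selections)))) {
    ox_stop("selections must be a named list")
  }
  for (nm in names(selections)) {
    if (!length(selections[[nm]])) ox_stop("empty selection: ", nm)
  }
  center_selection <- center_selection %||% membrane_center_indices(traj)
  nt <- n_frames(traj)
  half <- max(traj$box[, 3]) / 2
  edges <- seq(-(ceiling(half / bin_width) * bin_width),
               ceiling(half / bin_width) * bin_width, by = bin_width)
  centers <- edges[-1] - bin_width / 2
  acc <- matrix(0, length(centers), length(selections),
                dimnames = list(NULL, names(selections)))
  mass <- traj$atoms$mass
  for (t in seq_len(nt)) {
    z <- traj$coords[, 3, t]
    mcom <- sum(z[center_selection] * mass[center_selection]) /
      sum(mass[center_selection])
    area <- traj$box[t, 1] * traj$box[t, 2]
    for (j in seq_along(selections)) {
      sel <- selections[[j]]
      zi <- z[sel] - mcom
      bin <- findInterval(zi, edges, rightmost.closed = TRUE)
      ok <- bin >= 1L & bin <= length(centers)
      if (any(ok)) {
        sums <- rowsum(mass[sel][ok], bin[ok])
        acc[as.integer(rownames(sums)), j] <- acc[as.integer(rownames(sums)), j] +
          sums[, 1] / (bin_width * area)
      }
    }
  }
  dens <- acc / nt * ox_constants$AMU_PER_NM3_TO_KG_M3
  structure(list(bin_centers = centers, density = dens, bin_width = bin_width,
                 components = names(selections), n_frames = nt,
                 box_area = mean(traj$box[, 1] * traj$box[, 2])),
            class = "density_profile")
}

#' Water counts in symmetric zones about the membrane center
#'
#' @param traj an `md_trajectory`.
#' @param zone_width width of each zone (nm), default 0.4.
#' @param n_zones number of zones (zone i covers `|z| in [(i-1), i) *
#'   zone_width` from the membrane center).
#' @param water_selection atom indices of waters; default atoms with
#'   `resname == "SOL"`.
#' @return Matrix (frames x zones) of counts.
#' @export
water_zone_counts <- function(traj, zone_width = 0.4, n_zones = 5L,
                              water_selection = NULL) {
  if (zone_width <= 0) ox_stop("zone_width must be > 0")
  water_selection <- water_selection %||% select_atoms(traj, resname = "SOL")
  if (!length(water_selection)) ox_stop("empty selection: water")
  cen_sel <- membrane_center_indices(traj)
  mass <- traj$atoms$mass
  nt <- n_frames(traj)
  out <- matrix(0L, nt, n_zones,
                dimnames = list(NULL, paste0("zone", seq_len(n_zones))))
  for (t in seq_len(nt)) {
    z <- traj$coords[, 3, t]
    mcom <- sum(z[cen_sel] * mass[cen_sel]) / sum(mass[cen_sel])
    d <- abs(z[water_selection] - mcom)
    zone <- floor(d / zone_width) + 1L
    tabulated <- tabulate(zone[zone <= n_zones], nbins = n_zones)
    out[t, ] <- tabulated
  }
  out
}

## 3-bin moving average followed by a 3-point parabolic vertex fit around the
## maximum of one half-profile; gives sub-bin peak localization.
locate_peak <- function(z, y, label) {
  if (length(y) < 3L || max(y) <= 0 || diff(range(y)) < 1e-12) {
    ox_stop("no resolvable density peak in the ", label, " half-profile")
  }
  ys <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  i <- which.max(ys)
  if (i == 1L || i == length(ys)) return(z[i])
  y0 <- ys[i - 1L]; y1 <- ys[i]; y2 <- ys[i + 1L]
  denom <- (y0 - 2 * y1 + y2)
  if (abs(denom) < 1e-15) return(z[i])
  z[i] + 0.5 * (y0 - y2) / denom * (z[2] - z[1])
}

#' Bilayer thickness from phosphate density peaks
#'
#' Locates one density peak per half-space (inner z < 0, outer z > 0) by a
#' 3-point parabolic fit of the 3-bin-smoothed histogram maximum; thickness
#' is the peak-to-peak distance, with per-leaflet thickness measured from
#' each peak to the bilayer center.
#'
#' @param profile a `density_profile`.
#' @param component which component column to use (default first).
#' @return A `thickness_result`: `peak_inner`, `peak_outer` (nm),
#'   `thickness`, `leaflet_inner`, `leaflet_outer` (nm).
#' @export
membrane_thickness <- function(profile, component = NULL) {
  stopifnot(inherits(profile, "density_profile"))
  component <- component %||% profile$components[1]
  if (!component %in% profile$components) {
    ox_stop("profile has no component '", component, "'")
  }
  y <- profile$density[, component]
  z <- profile$bin_centers
  inner <- z < 0; outer <- z > 0
  if (!any(y[inner] > 0)) ox_stop("no resolvable density peak in the inner half-profile")
  if (!any(y[outer] > 0)) ox_stop("no resolvable density peak in the outer half-profile")
  p_in <- locate_peak(z[inner], y[inner], "inner")
  p_out <- locate_peak(z[outer], y[outer], "outer")
  structure(list(peak_inner = p_in, peak_outer = p_out,
                 thickness = p_out - p_in,
                 leaflet_inner = -p_in, leaflet_outer = p_out,
                 component = component),
            class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("thickness %.3f nm (inner leaflet %.3f, outer %.3f; peaks %.3f / %.3f nm)\n",
              x$thickness, x$leaflet_inner, x$leaflet_outer,
              x$peak_inner, x$peak_outer))
  invisible(x)
}

#' Area per lipid
#'
#' Lateral box area divided by the leaflet lipid count, per frame.
#'
#' @param traj an `md_trajectory`.
#' @param comp a `membrane_composition` supplying leaflet populations.
#' @param leaflet `"inner"` or `"outer"`.
#' @param include_cholesterol count cholesterol in the divisor?
#' @return List with `apl` (nm^2 time series) and `mean`.
#' @export
area_per_lipid <- function(traj, comp, leaflet = c("inner", "outer"),
                           include_cholesterol = FALSE) {
  leaflet <- match.arg(leaflet)
  tab <- comp$table[comp$table$leaflet == leaflet, ]
  n <- sum(tab$count[if (include_cholesterol) TRUE else tab$species != "CHOL"])
  if (n == 0L) ox_stop("zero lipids in ", leaflet, " leaflet")
  apl <- traj$box[, 1] * traj$box[, 2] / n
  list(apl = apl, mean = mean(apl), n_lipids = n)
}

## Peak position of one component in one half-space of a profile.
component_peak <- function(profile, component, side = c("inner", "outer")) {
  side <- match.arg(side)
  y <- profile$density[, component]
  z <- profile$bin_centers
  sel <- if (side == "inner") z < 0 else z > 0
  if (!any(y[sel] > 0)) ox_stop("no resolvable ", component, " peak in the ",
                                side, " half-profile")
  locate_peak(z[sel], y[sel], side)
}

#' Signed per-leaflet peak shift between two profiles
#'
#' Positive values mean the component's peak in `profileB` sits closer to the
#' membrane center than in `profileA`.
#'
#' @param profileA,profileB `density_profile`s containing `component`.
#' @param component component name.
#' @return Named numeric: `inner` and `outer` shifts (nm, positive = toward
#'   the center).
#' @export
profile_peak_shift <- function(profileA, profileB, component) {
  for (p in list(profileA, profileB)) {
    if (!component %in% p$components) {
      ox_stop("profile has no component '", component, "'")
    }
  }
  c(inner = abs(component_peak(profileA, component, "inner")) -
      abs(component_peak(profileB, component, "inner")),
    outer = abs(component_peak(profileA, component, "outer")) -
      abs(component_peak(profileB, component, "outer")))
}
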