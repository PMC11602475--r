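## Seeded synthetic-data generators.  Each generator is a pure function of
## (parameters, seed), returns data in the package's native containers, and
## attaches a `synthetic_truth` object recording the ground-truth parameters
## it used, so downstream estimators can be validated by parameter recovery.
## The generators target the statistical structure of bilayer trajectories
## (Gaussian layering, 2-D Brownian motion, biased Boltzmann sampling,
## Ornstein-Uhlenbeck force noise), not inter-lipid mechanics.

new_truth <- function(...) structure(list(...), class = "synthetic_truth")

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

## Rotation matrix for angle (rad) about unit axis u (Rodrigues).
rot_mat <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * (u %o% u)
}

#' Generate a Brownian bilayer trajectory with known diffusion constants
#'
#' One center-of-mass marker per lipid performs an independent 2-D Gaussian
#' random walk (per-step variance 2 D dt per axis) plus a shared per-leaflet
#' drift; z is fixed per leaflet. Coordinates are stored wrapped into the
#' box.
#'
#' @param comp a `membrane_composition` defining the lipid inventory.
#' @param D_by_species named numeric, diffusion constant per species
#'   (um^2/s); a single unnamed value applies to all species. Must be >= 0.
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing (ps).
#' @param leaflet_drift list with elements `inner` and `outer`, each a 2-vector
#'   drift velocity (nm/ps); default no drift.
#' @param box length-3 box (nm).
#' @param seed integer seed.
#' @return List with elements `trajectory` (`md_trajectory`) and `truth`
#'   (`synthetic_truth` with `D_by_species` in um^2/s, drift, dt, seed).
#' @export
gen_brownian_membrane <- function(comp, D_by_species, n_frames, dt,
                                  leaflet_drift = list(inner = c(0, 0),
                                                       outer = c(0, 0)),
                                  box = c(15, 15, 10), seed = 1L) {
  stopifnot(inherits(comp, "membrane_composition"), n_frames >= 2, dt > 0)
  if (any(D_by_species < 0)) ox_stop("diffusion constants must be >= 0")
  tab <- comp$table
  lip <- tab[rep(seq_len(nrow(tab)), tab$count), c("leaflet", "species")]
  n <- nrow(lip)
  D_nm <- if (is.null(names(D_by_species)) && length(D_by_species) == 1L) {
    rep(D_by_species, n)
  } else {
    miss <- setdiff(unique(lip$species), names(D_by_species))
    if (length(miss)) ox_stop("no diffusion constant for species: ",
                              paste(miss, collapse = ", "))
    unname(D_by_species[lip$species])
  }
  D_nm <- D_nm * ox_constants$UM2_S_TO_NM2_PS
  zc <- box[3] / 2
  z <- ifelse(lip$leaflet == "outer", zc + 1, zc - 1)
  coords <- with_seed(seed, {
    arr <- array(0, dim = c(n, 3L, n_frames))
    x <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]))
    drift <- rbind(inner = leaflet_drift$inner, outer = leaflet_drift$outer)
    vd <- drift[lip$leaflet, , drop = FALSE] * dt
    sd_step <- sqrt(2 * D_nm * dt)
    for (t in seq_len(n_frames)) {
      if (t > 1L) {
        x <- x + vd + cbind(stats::rnorm(n, 0, sd_step),
                            stats::rnorm(n, 0, sd_step))
      }
      arr[, 1, t] <- x[, 1] %% box[1]
      arr[, 2, t] <- x[, 2] %% box[2]
      arr[, 3, t] <- z
    }
    arr
  })
  atoms <- make_atoms(seq_len(n), lip$species, "P", 30.974,
                      species = lip$species, leaflet = lip$leaflet)
  traj <- md_trajectory(atoms, coords, (seq_len(n_frames) - 1) * dt, box)
  truth <- new_truth(D_by_species = D_by_species, leaflet_drift = leaflet_drift,
                     dt = dt, seed = seed)
  list(trajectory = traj, truth = truth)
}

## All-trans carbon skeleton along +z: lateral zigzag, skeletal (j-1 -> j+1)
## vectors exactly parallel to the chain axis.
all_trans_skeleton <- function(carbon_count, bond = 0.153, half_angle = 55.75) {
  h <- bond * sin(half_angle * pi / 180)
  a <- bond * cos(half_angle * pi / 180) / 2
  j <- seq_len(carbon_count)
  cbind(ifelse(j %% 2 == 0, a, -a), 0, (j - 1) * h)
}

#' Generate tilted acyl-chain ensembles with known orientation
#'
#' Builds all-trans carbon skeletons, optionally introduces gauche defects,
#' and tilts each chain by the requested angle about a random azimuth. With
#' `gauche_fraction = 0` and tilt t, every internal skeletal axis
#' (C(j-1) -> C(j+1)) makes exactly angle t with z, so the deuterium order
#' parameter is (3 cos^2 t - 1)/2 analytically at every internal carbon.
#'
#' @param n_chains number of chains.
#' @param carbon_count carbons per chain (>= 3).
#' @param tilt_deg tilt angle in degrees in `[0, 90]`, or `"isotropic"` for
#'   uniformly random chain orientations on the sphere.
#' @param gauche_fraction probability of a +/-120 degree dihedral defect per
#'   internal bond.
#' @param seed integer seed.
#' @return List with `frame` (`md_frame`; atoms grouped by `resid` = chain)
#'   and `truth` (imposed tilts per chain, gauche fraction, seed).
#' @export
gen_ordered_chains <- function(n_chains, carbon_count, tilt_deg = 0,
                               gauche_fraction = 0, seed = 1L) {
  stopifnot(n_chains >= 1, carbon_count >= 3)
  isotropic <- identical(tilt_deg, "isotropic")
  if (!isotropic) {
    stopifnot(is.numeric(tilt_deg), tilt_deg >= 0, tilt_deg <= 90)
  }
  base <- all_trans_skeleton(carbon_count)
  grid_n <- ceiling(sqrt(n_chains))
  spacing <- 2 + 0.153 * carbon_count
  out <- with_seed(seed, {
    chains <- vector("list", n_chains)
    tilts <- numeric(n_chains)
    for (i in seq_len(n_chains)) {
      xyz <- base
      if (gauche_fraction > 0) {
        for (jb in 2:(carbon_count - 1L)) {
          if (stats::runif(1) < gauche_fraction) {
            axis <- xyz[jb, ] - xyz[jb - 1L, ]
            Rg <- rot_mat(axis, sample(c(-1, 1), 1L) * 2 * pi / 3)
            seg <- (jb + 1L):carbon_count
            xyz[seg, ] <- sweep(sweep(xyz[seg, , drop = FALSE], 2, xyz[jb, ]) %*%
                                  t(Rg), 2, xyz[jb, ], `+`)
          }
        }
      }
      if (isotropic) {
        ## uniform orientation: rotate z-axis to a uniform direction, then a
        ## uniform spin about it
        v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
        ax <- c(-v[2], v[1], 0)
        R <- if (sqrt(sum(ax^2)) < 1e-12) diag(3) * sign(v[3]) else
          rot_mat(ax, acos(max(-1, min(1, v[3]))))
        R <- R %*% rot_mat(c(0, 0, 1), stats::runif(1, 0, 2 * pi))
        tilts[i] <- acos(max(-1, min(1, v[3]))) * 180 / pi
      } else {
        phi <- stats::runif(1, 0, 2 * pi)
        R <- rot_mat(c(cos(phi), sin(phi), 0), tilt_deg * pi / 180)
        tilts[i] <- tilt_deg
      }
      xyz <- xyz %*% t(R)
      xyz[, 1] <- xyz[, 1] + ((i - 1L) %% grid_n) * spacing + spacing / 2
      xyz[, 2] <- xyz[, 2] + ((i - 1L) %/% grid_n) * spacing + spacing / 2
      xyz[, 3] <- xyz[, 3] + spacing
      chains[[i]] <- xyz
    }
    list(xyz = do.call(rbind, chains), tilts = tilts)
  })
  atoms <- make_atoms(rep(seq_len(n_chains), each = carbon_count), "CHN",
                      paste0("C", rep(seq_len(carbon_count), n_chains)),
                      12.011)
  box <- rep(grid_n * spacing + 2 * spacing, 3)
  frame <- md_frame(out$xyz, box, 0, atoms)
  truth <- new_truth(imposed_tilts = out$tilts,
                     gauche_fraction = gauche_fraction, seed = seed)
  list(frame = frame, truth = truth)
}

#' Generate a Gaussian-layered bilayer trajectory
#'
#' Component z-coordinates are drawn from leaflet-mirrored Gaussians about
#' the membrane center (phosphates at +/- z_P, carbonyls nearer the center,
#' terminal methyls around it); waters are uniform outside a central
#' exclusion slab. Frames are independent draws, which is what density-profile
#' estimators average over.
#'
#' @param comp a `membrane_composition`; one marker atom per lipid per
#'   component that applies to it (phosphate markers for phospholipids, O3
#'   markers for cholesterol).
#' @param layers named list of `list(mean, sigma, mass, name)` per component;
#'   `mean` is the unsigned distance of the layer from the membrane center
#'   (nm), mirrored across leaflets. Defaults give phosphates at 2.26 nm.
#' @param n_frames number of frames.
#' @param n_waters number of water markers.
#' @param water_exclusion_halfwidth waters are excluded from
#'   `|z - center| <=` this halfwidth (nm).
#' @param box length-3 box (nm).
#' @param seed integer seed.
#' @return List with `trajectory` and `truth` (layer means/sigmas, water
#'   parameters, seed).
#' @export
gen_layered_bilayer <- function(comp,
                                layers = list(
                                  phosphate = list(mean = 2.26, sigma = 0.15,
                                                   mass = 94.97, name = "P"),
                                  carbonyl  = list(mean = 1.60, sigma = 0.18,
                                                   mass = 28.01, name = "C1"),
                                  methyl    = list(mean = 0.35, sigma = 0.30,
                                                   mass = 15.04, name = "C16"),
                                  chol      = list(mean = 1.20, sigma = 0.30,
                                                   mass = 17.01, name = "O3")),
                                n_frames = 50, n_waters = 2000,
                                water_exclusion_halfwidth = 2.0,
                                box = c(8, 8, 10), seed = 1L) {
  stopifnot(inherits(comp, "membrane_composition"), n_frames >= 1)
  for (ly in layers) if (ly$sigma <= 0) ox_stop("layer sigma must be > 0")
  tab <- comp$table
  lip <- tab[rep(seq_len(nrow(tab)), tab$count), c("leaflet", "species")]
  is_chol <- lip$species == "CHOL"
  rows <- list()
  for (cname in names(layers)) {
    sel <- if (cname == "chol") is_chol else if (cname %in% c("phosphate")) !is_chol
    else if (cname %in% c("carbonyl", "methyl")) !is_chol else rep(TRUE, nrow(lip))
    if (!any(sel)) next
    rows[[cname]] <- data.frame(component = cname,
                                leaflet = lip$leaflet[sel],
                                species = lip$species[sel],
                                mass = layers[[cname]]$mass,
                                name = layers[[cname]]$name,
                                mean = layers[[cname]]$mean,
                                sigma = layers[[cname]]$sigma)
  }
  mk <- do.call(rbind, rows)
  n_mk <- nrow(mk)
  zc <- box[3] / 2
  sgn <- ifelse(mk$leaflet == "outer", 1, -1)
  coords <- with_seed(seed, {
    arr <- array(0, dim = c(n_mk + n_waters, 3L, n_frames))
    for (t in seq_len(n_frames)) {
      arr[1:n_mk, 1, t] <- stats::runif(n_mk, 0, box[1])
      arr[1:n_mk, 2, t] <- stats::runif(n_mk, 0, box[2])
      arr[1:n_mk, 3, t] <- zc + sgn * stats::rnorm(n_mk, mk$mean, mk$sigma)
      if (n_waters > 0) {
        half_out <- box[3] / 2 - water_exclusion_halfwidth
        if (half_out <= 0) ox_stop("water exclusion slab fills the box")
        u <- stats::runif(n_waters, -half_out, half_out)
        zw <- zc + sign(u) * water_exclusion_halfwidth + u
        arr[(n_mk + 1):(n_mk + n_waters), 1, t] <- stats::runif(n_waters, 0, box[1])
        arr[(n_mk + 1):(n_mk + n_waters), 2, t] <- stats::runif(n_waters, 0, box[2])
        arr[(n_mk + 1):(n_mk + n_waters), 3, t] <- zw %% box[3]
      }
    }
    arr
  })
  atoms <- make_atoms(
    resid = seq_len(n_mk + n_waters),
    resname = c(mk$component, rep("SOL", n_waters)),
    name = c(mk$name, rep("OW", n_waters)),
    mass = c(mk$mass, rep(18.015, n_waters)),
    species = c(mk$species, rep("SOL", n_waters)),
    leaflet = c(mk$leaflet, rep(NA_character_, n_waters)))
  traj <- md_trajectory(atoms, coords, seq_len(n_frames) - 1, box)
  truth <- new_truth(layer_means = vapply(layers, `[[`, 0, "mean"),
                     layer_sigmas = vapply(layers, `[[`, 0, "sigma"),
                     n_waters = n_waters,
                     water_exclusion_halfwidth = water_exclusion_halfwidth,
                     seed = seed)
  list(trajectory = traj, truth = truth)
}

#' Generate biased umbrella-window samples from a known free-energy profile
#'
#' Samples each window exactly from the biased Boltzmann density
#' p_i(z) proportional to exp(-(G(z) + k/2 (z - z_i)^2)/kT) by inverse-CDF
#' sampling on a fine grid (rejection-free, reproducible). The exact biased
#' densities are retained in the truth object for oracle comparisons.
#'
#' @param pmf_true function of z returning the true free energy (kJ/mol).
#' @param window_centers numeric window centers (nm).
#' @param force_constant harmonic force constant (kJ mol^-1 nm^-2), >= 0.
#' @param n_per_window samples per window.
#' @param kT thermal energy (kJ/mol).
#' @param dt sample spacing (ps), cosmetic.
#' @param grid_points inverse-CDF grid size per window.
#' @param sample_range explicit sampling range, required when
#'   `force_constant = 0`; otherwise each window spans its center +/- 6
#'   bias standard deviations (widened by the local PMF scale).
#' @param seed integer seed.
#' @return List with `windows` (list of `window_series`) and `truth`
#'   (pmf grid/values, exact biased densities, parameters, seed).
#' @export
gen_umbrella_samples <- function(pmf_true, window_centers, force_constant,
                                 n_per_window, kT, dt = 1,
                                 grid_points = 10000L, sample_range = NULL,
                                 seed = 1L) {
  if (force_constant < 0) ox_stop("force constant must be >= 0")
  stopifnot(is.function(pmf_true), n_per_window >= 1, kT > 0)
  if (force_constant == 0 && is.null(sample_range)) {
    ox_stop("sample_range is required when force_constant = 0")
  }
  densities <- vector("list", length(window_centers))
  windows <- with_seed(seed, {
    lapply(seq_along(window_centers), function(i) {
      zc <- window_centers[i]
      rng <- if (!is.null(sample_range)) sample_range else {
        half <- 6 * sqrt(kT / force_constant) + 0.2
        c(zc - half, zc + half)
      }
      grid <- seq(rng[1], rng[2], length.out = grid_points)
      G <- pmf_true(grid)
      if (any(!is.finite(G))) ox_stop("pmf_true must be finite on the sampling range")
      u_bias <- 0.5 * force_constant * (grid - zc)^2
      logw <- -(G + u_bias) / kT
      w <- exp(logw - max(logw))
      w <- w / sum(w)
      densities[[i]] <<- list(z = grid, p = w / (grid[2] - grid[1]))
      cdf <- cumsum(w)
      u <- stats::runif(n_per_window)
      z <- stats::approx(cdf, grid, xout = u, rule = 2, ties = "ordered")$y
      window_series(zc, force_constant, seq_len(n_per_window) * dt, z)
    })
  })
  truth <- new_truth(pmf_true = pmf_true, window_centers = window_centers,
                     force_constant = force_constant, kT = kT,
                     biased_densities = densities, seed = seed)
  list(windows = windows, truth = truth)
}

#' Generate stationary force series with known autocorrelation integral
#'
#' Ornstein-Uhlenbeck series with autocovariance sigma^2 exp(-t/tau), where
#' sigma^2 tau = (RT)^2 / D_target, so the force-autocorrelation diffusion
#' estimator should recover `D_target` at each position.
#'
#' @param D_target numeric vector of target diffusion constants (nm^2/ps),
#'   one per window/position.
#' @param z positions (nm) the series belong to (same length as `D_target`).
#' @param T_K temperature (K).
#' @param tau autocorrelation time (ps), must exceed `2 * dt` (shorter series
#'   are under-resolved and rejected).
#' @param n samples per series.
#' @param dt sample spacing (ps).
#' @param seed integer seed.
#' @return List with `series` (list of `list(z, time, force)`) and `truth`
#'   (`D_target`, `sigma2`, `tau`, `T_K`, seed).
#' @export
gen_force_series <- function(D_target, z = seq_along(D_target), T_K = 298,
                             tau = 1, n = 150000L, dt = 0.05, seed = 1L) {
  if (tau <= 0) ox_stop("tau must be > 0")
  if (tau <= 2 * dt) ox_stop("under-resolved: tau must exceed 2 * dt")
  stopifnot(all(D_target > 0), length(z) == length(D_target))
  RT <- ox_kT(T_K)
  sigma2 <- RT^2 / (D_target * tau)
  rho <- exp(-dt / tau)
  series <- with_seed(seed, {
    lapply(seq_along(D_target), function(i) {
      s <- sqrt(sigma2[i])
      innov <- c(stats::rnorm(1, 0, s),
                 stats::rnorm(n - 1L, 0, s * sqrt(1 - rho^2)))
      f <- as.numeric(stats::filter(innov, rho, method = "recursive"))
      list(z = z[i], time = (seq_len(n) - 1) * dt, force = f)
    })
  })
  truth <- new_truth(D_target = D_target, sigma2 = sigma2, tau = tau,
                     T_K = T_K, dt = dt, seed = seed)
  list(series = series, truth = truth)
}

#' Generate a hydrogen-bond fixture with a known number of bonds
#'
#' Plants exactly `k_bonds` donor-H-acceptor triplets satisfying the
#' detection criteria and `k_nonbonds` triplets violating them by the stated
#' margins (alternating distance and angle violations). Triplets are placed
#' on a coarse grid so no accidental cross-pair bonds arise.
#'
#' @param k_bonds number of bonded triplets.
#' @param k_nonbonds number of non-bonded triplets.
#' @param criteria an [hbond_criteria()] object.
#' @param distance_margin,angle_margin margins (nm, degrees) by which
#'   non-bonds violate / bonds satisfy the criteria; both must be > 0
#'   (a zero margin would make the fixture ambiguous).
#' @param seed integer seed.
#' @return List with `frame`, `donors` (data.frame `D`, `H` atom indices),
#'   `acceptors` (atom indices) and `truth` (`k_bonds`, seed).
#' @export
gen_hbond_fixture <- function(k_bonds, k_nonbonds,
                              criteria = hbond_criteria(),
                              distance_margin = 0.05, angle_margin = 10,
                              seed = 1L) {
  if (distance_margin <= 0 || angle_margin <= 0) {
    ox_stop("ambiguous fixture: margins must be > 0")
  }
  n <- k_bonds + k_nonbonds
  cell <- criteria$max_DA_distance + distance_margin + 1.5
  grid_n <- max(1L, ceiling(sqrt(max(n, 1L))))
  box <- rep(grid_n * cell + cell, 3)
  coords <- matrix(0, nrow = 3L * n, ncol = 3L)
  rows <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      origin <- c(((i - 1L) %% grid_n) + 0.5, ((i - 1L) %/% grid_n) + 0.5, 0.5) * cell
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      bonded <- i <= k_bonds
      if (bonded) {
        dDA <- criteria$max_DA_distance - distance_margin
        theta <- stats::runif(1, 0, max(criteria$max_HDA_angle - angle_margin, 0))
      } else if ((i - k_bonds) %% 2L == 1L) {
        dDA <- criteria$max_DA_distance + distance_margin
        theta <- 0
      } else {
        dDA <- criteria$max_DA_distance - distance_margin
        theta <- min(criteria$max_HDA_angle + angle_margin, 179)
      }
      ## perpendicular direction for the H placement
      p <- c(-u[2], u[1], 0)
      if (sqrt(sum(p^2)) < 1e-9) p <- c(1, 0, 0)
      p <- p / sqrt(sum(p^2))
      h_dir <- cos(theta * pi / 180) * u + sin(theta * pi / 180) * p
      D <- origin
      A <- origin + dDA * u
      H <- origin + 0.1 * h_dir
      rbind(D, H, A)
    })
  })
  for (i in seq_len(n)) coords[(3 * i - 2):(3 * i), ] <- rows[[i]]
  if (n == 0L) {
    coords <- matrix(numeric(), ncol = 3L)
    atoms <- make_atoms(integer(), character(), character(), numeric())
  } else {
    atoms <- make_atoms(rep(seq_len(n), each = 3L), "FIX",
                        rep(c("OD", "HD", "OA"), n),
                        rep(c(15.999, 1.008, 15.999), n))
  }
  frame <- md_frame(coords, box, 0, atoms)
  donors <- data.frame(D = seq_len(n) * 3L - 2L, H = seq_len(n) * 3L - 1L)
  acceptors <- seq_len(n) * 3L
  list(frame = frame, donors = donors, acceptors = acceptors,
       truth = new_truth(k_bonds = k_bonds, k_nonbonds = k_nonbonds,
                         seed = seed))
}
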