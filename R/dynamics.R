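## Lateral diffusion: PBC unwrapping with monolayer / membrane
## center-of-mass correction, time-averaged lateral MSD (naive and
## FFT-based estimators), Einstein-relation diffusion coefficients, and the
## free-area-theory diagnostic.

#' Unwrap lipid tracks and remove collective motion
#'
#' Produces per-lipid xy center-of-mass tracks: periodic-boundary unwrapped
#' (consecutive displacements minimum-imaged), then corrected by removing
#' the whole-membrane COM displacement followed by the per-leaflet residual
#' COM displacement (order recorded in the result).
#'
#' @param traj an `md_trajectory` whose atoms carry `leaflet` tags and
#'   `resid` grouping (one lipid per residue id).
#' @return A `lipid_tracks` object: `xy` (lipids x 2 x frames, nm),
#'   `species`, `leaflet`, `times` (ps), `correction` (character).
#' @export
unwrap_and_correct <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  a <- traj$atoms
  if (any(is.na(a$leaflet))) {
    ox_stop("untagged lipid(s): residues ",
            paste(utils::head(unique(a$resid[is.na(a$leaflet)]), 5), collapse = ", "))
  }
  nt <- n_frames(traj)
  ## unwrap atoms: minimum-image consecutive displacements, cumulated
  ux <- traj$coords[, 1:2, , drop = FALSE]
  for (t in 2:nt) {
    d <- ux[, 1:2, t] - ux[, 1:2, t - 1L]
    for (k in 1:2) d[, k] <- d[, k] - traj$box[t, k] * round(d[, k] / traj$box[t, k])
    ux[, 1:2, t] <- ux[, 1:2, t - 1L] + d
  }
  ## per-lipid COM (mass weighted within residue)
  rid <- a$resid
  lip_ids <- unique(rid)
  nl <- length(lip_ids)
  slice2 <- function(arr, rows, k) {
    m <- arr[rows, k, , drop = FALSE]
    dim(m) <- c(length(rows), dim(arr)[3])
    m
  }
  xy <- array(0, dim = c(nl, 2L, nt))
  w <- a$mass
  for (li in seq_len(nl)) {
    rows <- which(rid == lip_ids[li])
    wr <- w[rows] / sum(w[rows])
    for (k in 1:2) xy[li, k, ] <- colSums(slice2(ux, rows, k) * wr)
  }
  species <- a$species[match(lip_ids, rid)]
  leaflet <- a$leaflet[match(lip_ids, rid)]
  lip_mass <- vapply(lip_ids, function(id) sum(w[rid == id]), 0)
  ## whole-membrane COM displacement, then leaflet residual
  wm <- lip_mass / sum(lip_mass)
  for (k in 1:2) {
    com <- colSums(slice2(xy, seq_len(nl), k) * wm)
    xy[, k, ] <- xy[, k, ] - matrix(com - com[1], nl, nt, byrow = TRUE)
  }
  for (lf in unique(leaflet)) {
    sel <- which(leaflet == lf)
    wl <- lip_mass[sel] / sum(lip_mass[sel])
    for (k in 1:2) {
      com <- colSums(slice2(xy, sel, k) * wl)
      xy[sel, k, ] <- xy[sel, k, ] - matrix(com - com[1], length(sel), nt,
                                            byrow = TRUE)
    }
  }
  structure(list(xy = xy, species = species, leaflet = leaflet,
                 times = traj$times,
                 correction = "membrane-COM then leaflet-COM"),
            class = "lipid_tracks")
}

## FFT-based time-averaged MSD of one track (T x 2 matrix); O(T log T).
msd_fft_single <- function(x) {
  n <- nrow(x)
  ## MSD is shift-invariant; centering shrinks the FFT's dynamic range and
  ## with it the cancellation error
  x <- sweep(x, 2, colMeans(x))
  D <- rowSums(x^2)
  S2 <- numeric(n)
  for (k in seq_len(ncol(x))) {
    f <- stats::fft(c(x[, k], numeric(n)))
    ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:n] / (2 * n)
    S2 <- S2 + ac
  }
  S2 <- S2 / (n - 0:(n - 1L))
  Q <- 2 * sum(D)
  S1 <- numeric(n)
  for (m in 0:(n - 1L)) {
    if (m > 0L) Q <- Q - D[m] - D[n - m + 1L]
    S1[m + 1L] <- Q / (n - m)
  }
  S1 - 2 * S2
}

## Naive O(T^2) sliding-window MSD; the independent reference estimator.
msd_naive_single <- function(x) {
  n <- nrow(x)
  vapply(0:(n - 1L), function(m) {
    if (m == 0L) return(0)
    d <- x[(m + 1L):n, , drop = FALSE] - x[1:(n - m), , drop = FALSE]
    mean(rowSums(d^2))
  }, 0)
}

#' Lateral mean-square displacement
#'
#' Time- and ensemble-averaged squared xy displacement per lag
#' (sliding-window averaging over all time origins).
#'
#' @param tracks a `lipid_tracks` object.
#' @param max_lag_fraction largest lag as a fraction of the trajectory
#'   length (default 0.05: the time-averaged MSD is most reliable well below
#'   the trajectory length, where every lag still has many origin pairs;
#'   raise it to inspect the long-lag regime).
#' @param method `"fft"` (default, O(T log T)) or `"naive"` (O(T^2)); the
#'   two agree to numerical precision.
#' @return An `msd_series`: `lag` (ps), `per_lipid` (lipids x lags matrix,
#'   nm^2), `msd` (ensemble mean), `n_pairs` (origin pairs per lag, summed
#'   over lipids), `species`, `leaflet`, `by_group` (data.frame of per
#'   species-leaflet ensemble MSD).
#' @export
msd_lateral <- function(tracks, max_lag_fraction = 0.05,
                        method = c("fft", "naive")) {
  stopifnot(inherits(tracks, "lipid_tracks"))
  method <- match.arg(method)
  nt <- dim(tracks$xy)[3]
  if (nt < 2L) ox_stop("need >= 2 frames for MSD")
  n_lag <- max(2L, floor(nt * max_lag_fraction))
  if (n_lag > nt) {
    warning("lag schedule exceeds trajectory; dropping to trajectory length",
            call. = FALSE)
    n_lag <- nt
  }
  nl <- dim(tracks$xy)[1]
  per <- matrix(0, nl, n_lag)
  for (li in seq_len(nl)) {
    x <- t(tracks$xy[li, , ])
    full <- switch(method, fft = msd_fft_single(x), naive = msd_naive_single(x))
    per[li, ] <- full[seq_len(n_lag)]
  }
  lag <- (seq_len(n_lag) - 1L) * (tracks$times[2] - tracks$times[1])
  grp <- interaction(tracks$species, tracks$leaflet, drop = TRUE, sep = "/")
  by_group <- do.call(rbind, lapply(levels(grp), function(g) {
    rows <- which(grp == g)
    data.frame(group = g, lag = lag,
               msd = colMeans(per[rows, , drop = FALSE]),
               n_lipids = length(rows))
  }))
  structure(list(lag = lag, per_lipid = per,
                 msd = colMeans(per),
                 n_pairs = nl * (nt - (seq_len(n_lag) - 1L)),
                 species = tracks$species, leaflet = tracks$leaflet,
                 by_group = by_group, method = method),
            class = "msd_series")
}

fit_D <- function(lag, msd, window) {
  sel <- lag >= window[1] & lag <= window[2]
  if (sum(sel) < 5L) ox_stop("fit window contains fewer than 5 lags")
  fit <- stats::lm(msd[sel] ~ lag[sel])
  slope <- unname(stats::coef(fit)[2])
  ## analytic inputs give perfect fits; silence the harmless lm warning
  sm <- suppressWarnings(summary(fit))
  list(D = slope / 4 / ox_constants$UM2_S_TO_NM2_PS,
       se = sm$coefficients[2, 2] / 4 / ox_constants$UM2_S_TO_NM2_PS,
       r2 = sm$r.squared)
}

#' Einstein-relation diffusion coefficient from an MSD series
#'
#' Least-squares slope of the lateral MSD over the fit window, divided by 4
#' (2-D Einstein relation), in um^2/s. The pooled (ensemble-MSD) fit gives
#' the headline estimate; per-lipid fits give the mean +/- SD across lipids,
#' reflecting the large lipid-to-lipid spread seen in bilayer simulations.
#' Negative estimates are reported and flagged, never clipped.
#'
#' @param msd an `msd_series`.
#' @param fit_fraction two fractions of the maximum lag delimiting the fit
#'   window (default 0.1 to 0.5, avoiding the short-time and
#'   poor-statistics long-time regimes).
#' @return A `diffusion_estimate`: `D` (um^2/s, pooled), `se`, `r2`,
#'   `fit_window` (ps), `per_lipid` (data.frame `species`, `leaflet`, `D`),
#'   `D_mean`, `D_sd` (across lipids), `negative_flag`.
#' @export
diffusion_coefficient <- function(msd, fit_fraction = c(0.1, 0.5)) {
  stopifnot(inherits(msd, "msd_series"))
  stopifnot(length(fit_fraction) == 2L, fit_fraction[1] < fit_fraction[2])
  window <- range(msd$lag) [2] * fit_fraction
  pooled <- fit_D(msd$lag, msd$msd, window)
  per <- vapply(seq_len(nrow(msd$per_lipid)), function(i) {
    fit_D(msd$lag, msd$per_lipid[i, ], window)$D
  }, 0)
  per_df <- data.frame(species = msd$species, leaflet = msd$leaflet, D = per)
  structure(list(D = pooled$D, se = pooled$se, r2 = pooled$r2,
                 fit_window = window, per_lipid = per_df,
                 D_mean = mean(per), D_sd = stats::sd(per),
                 negative_flag = pooled$D < 0 || any(per < 0)),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.3g um^2/s (pooled, r^2 = %.3f); per-lipid %.3g +/- %.3g um^2/s%s\n",
              x$D, x$r2, x$D_mean, x$D_sd,
              if (x$negative_flag) " [negative estimates flagged]" else ""))
  invisible(x)
}

#' Free-area-theory relative diffusion ratio
#'
#' Ratio of exp(-a_l/a_f) factors between a membrane state and a reference
#' state: the free-area theory's prediction for the relative lateral
#' mobility. Diagnostic only.
#'
#' @param inputs,reference lists with `a_l` (cross-sectional area per lipid,
#'   nm^2) and `a_f` (free area per molecule, nm^2), both > 0.
#' @return Numeric ratio (1 when inputs equal the reference).
#' @export
free_area_relative_D <- function(inputs, reference) {
  for (x in list(inputs, reference)) {
    if (x$a_l <= 0 || x$a_f <= 0) ox_stop("a_l and a_f must be > 0")
  }
  exp(-inputs$a_l / inputs$a_f) / exp(-reference$a_l / reference$a_f)
}
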