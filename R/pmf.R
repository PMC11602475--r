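## Umbrella sampling -> free energy -> permeability.
##
## WHAM: self-consistent unbiasing of window histograms,
##   p(z) = sum_i n_i(z) / sum_i N_i f_i^-1 exp(-U_i(z)/kT),
##   f_i^-1 = sum_z p(z) exp(-U_i(z)/kT),
## iterated until the largest change in the window free energies
## (-kT ln f_i) falls below tol; Delta G(z) = -kT ln p(z), anchored to zero
## over the bulk plateau on the starting (outer aqueous) side.
##
## Permeability: inhomogeneous solubility-diffusion model,
##   P = [ integral exp(DeltaG(z)/RT) / D(z) dz ]^-1,
## with D(z) from the force-autocorrelation method,
##   D(z_i) = (RT)^2 / integral_0^inf <dF(t) dF(0)> dt.

#' Umbrella window schedule
#'
#' Window centers from `z_start` toward `z_end` at the given spacing (the
#' half-open convention: centers are `z_start, z_start - spacing, ...`,
#' stopping before passing `z_end`), each carrying the harmonic bias
#' constant. The defaults give the canonical 40-window, 0.2 nm,
#' 100 kJ/mol/nm^2 pulling schedule from the outer aqueous phase (z = 4 nm)
#' to the inner (z = -4 nm).
#'
#' @param z_start,z_end span of the pull (nm).
#' @param spacing window spacing (nm), > 0.
#' @param k harmonic force constant (kJ mol^-1 nm^-2).
#' @return data.frame with columns `center` and `k`.
#' @export
make_window_schedule <- function(z_start = 4.0, z_end = -4.0, spacing = 0.2,
                                 k = 100) {
  if (spacing <= 0) ox_stop("spacing must be > 0")
  span <- abs(z_end - z_start)
  if (span == 0) ox_stop("zero-span schedule")
  n <- floor(span / spacing + 1e-9)
  centers <- z_start + sign(z_end - z_start) * spacing * (seq_len(n) - 1L)
  data.frame(center = centers, k = k)
}

#' Discard the equilibration phase of a window series
#'
#' @param series a `window_series`.
#' @param trim_fraction leading fraction of samples to drop, in [0, 1);
#'   default 0.5 (first half as equilibration).
#' @return The trimmed `window_series`.
#' @export
equilibration_trim <- function(series, trim_fraction = 0.5) {
  stopifnot(inherits(series, "window_series"))
  if (trim_fraction < 0 || trim_fraction >= 1) {
    ox_stop("trim_fraction must be in [0, 1)")
  }
  n <- length(series$z)
  drop <- floor(n * trim_fraction)
  if (drop >= n) ox_stop("trim would leave no samples")
  keep <- (drop + 1L):n
  window_series(series$center, series$force_constant,
                series$time[keep], series$z[keep],
                if (!is.null(series$force)) series$force[keep])
}

#' Weighted histogram analysis of umbrella windows
#'
#' @param windows list of `window_series`.
#' @param bin_width histogram bin width (nm), default 0.05.
#' @param kT thermal energy (kJ/mol).
#' @param tol convergence tolerance: largest change of any window free
#'   energy (-kT ln f_i) per iteration, kJ/mol.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param min_overlap minimum number of jointly occupied bins required
#'   between adjacent windows (sampling-gap guard).
#' @param min_count bins with fewer total samples than this are treated as
#'   unsampled and dropped from the profile (a bin with a handful of counts
#'   carries no usable free-energy information); default 10.
#' @param anchor `"start"` (default): zero the profile on the mean over the
#'   outermost `anchor_width` nm of the sampled range on the first window's
#'   side; `"min"`: zero at the minimum.
#' @param anchor_width width of the bulk anchoring plateau (nm).
#' @param z_range span over which the profile is reported; defaults to the
#'   range of window centers (the scheduled pull span). Histogram mass in
#'   the bias tails beyond the outermost centers is kept for the
#'   self-consistent solve but not reported, as those bins are sampled only
#'   through the tails of the end windows.
#' @return A `pmf_profile`: `z` (bin centers, sampled bins only), `G`
#'   (kJ/mol), `se` (per-bin statistical scale, kJ/mol), `kT`, `n_iter`,
#'   `counts` (total samples per bin), plus the anchoring convention.
#'   Unsampled interior bins are absent from the grid, never interpolated.
#' @export
wham <- function(windows, bin_width = 0.05, kT = ox_kT(298), tol = 1e-6,
                 max_iter = 50000L, min_overlap = 1L, min_count = 10L,
                 anchor = c("start", "min"), anchor_width = 0.5,
                 z_range = NULL) {
  anchor <- match.arg(anchor)
  stopifnot(length(windows) >= 1L, bin_width > 0, kT > 0)
  zall <- unlist(lapply(windows, `[[`, "z"))
  lo <- floor(min(zall) / bin_width) * bin_width
  hi <- ceiling(max(zall) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  z <- edges[-1] - bin_width / 2
  nb <- length(z)
  nw <- length(windows)
  counts <- matrix(0, nb, nw)
  for (i in seq_len(nw)) {
    b <- findInterval(windows[[i]]$z, edges, rightmost.closed = TRUE)
    counts[, i] <- tabulate(b[b >= 1L & b <= nb], nbins = nb)
  }
  ## adjacent-window overlap guard (windows ordered by center)
  ord <- order(vapply(windows, `[[`, 0, "center"))
  for (j in seq_len(nw - 1L)) {
    a <- ord[j]; b <- ord[j + 1L]
    joint <- sum(counts[, a] > 0 & counts[, b] > 0)
    if (joint < min_overlap) {
      ox_stop("no histogram overlap between windows centered at ",
              windows[[a]]$center, " and ", windows[[b]]$center, " nm")
    }
  }
  Ni <- colSums(counts)
  n_z <- rowSums(counts)
  ## bias energies U_i(z): nb x nw
  U <- vapply(seq_len(nw), function(i) {
    0.5 * windows[[i]]$force_constant * (z - windows[[i]]$center)^2
  }, numeric(nb))
  expU <- exp(-U / kT)
  finv <- rep(1, nw)       # f_i^-1 = sum_z p(z) exp(-U_i/kT) * dz
  g_old <- rep(0, nw)
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    denom <- as.vector(expU %*% (Ni / finv))
    p <- ifelse(denom > 0, n_z / denom, 0)
    finv <- as.vector(crossprod(expU, p))
    g_new <- -kT * log(finv)
    g_new <- g_new - g_new[1]
    delta <- max(abs(g_new - g_old))
    g_old <- g_new
    if (delta < tol) break
    if (n_iter >= max_iter) {
      ox_stop("WHAM did not converge in ", max_iter,
              " iterations (residual ", format(delta, digits = 3), " kJ/mol)")
    }
  }
  z_range <- z_range %||% range(vapply(windows, `[[`, 0, "center"))
  sampled <- n_z >= max(1L, min_count) & z >= z_range[1] - bin_width / 2 &
    z <= z_range[2] + bin_width / 2
  G <- -kT * log(p[sampled])
  zs <- z[sampled]
  ## anchor to the bulk plateau on the starting side
  if (anchor == "start") {
    start_side <- windows[[1]]$center
    if (abs(start_side - max(zs)) <= abs(start_side - min(zs))) {
      plateau <- zs >= max(zs) - anchor_width
    } else {
      plateau <- zs <= min(zs) + anchor_width
    }
    G <- G - mean(G[plateau])
  } else {
    G <- G - min(G)
  }
  se <- ifelse(n_z[sampled] > 0, kT / sqrt(n_z[sampled]), NA_real_)
  structure(list(z = zs, G = G, se = se, kT = kT, n_iter = n_iter,
                 counts = n_z[sampled], bin_width = bin_width,
                 anchor = anchor, anchor_width = anchor_width),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("pmf_profile: %d bins over [%.2f, %.2f] nm, barrier %.2f kJ/mol (%d WHAM iterations)\n",
              length(x$z), min(x$z), max(x$z), max(x$G), x$n_iter))
  invisible(x)
}

#' Free-energy barrier readouts of a PMF profile
#'
#' @param pmf a `pmf_profile`.
#' @return List: `barrier_vs_bulk` (peak minus the anchored bulk zero) and
#'   `barrier_vs_minimum` (peak minus the interfacial minimum); both
#'   conventions appear in the permeation literature.
#' @export
pmf_barrier <- function(pmf) {
  list(barrier_vs_bulk = max(pmf$G),
       barrier_vs_minimum = max(pmf$G) - min(pmf$G))
}

## FFT-based autocovariance (biased normalization 1/n), lags 0..nlag.
acov_fft <- function(f, nlag) {
  n <- length(f)
  m <- stats::nextn(2L * n)
  ff <- stats::fft(c(f, numeric(m - n)))
  ac <- Re(stats::fft(ff * Conj(ff), inverse = TRUE))[seq_len(nlag + 1L)] / m
  ac / n
}

#' Position-dependent diffusion from force autocorrelation
#'
#' D(z_i) = (RT)^2 / integral_0^inf <dF(t) dF(0)> dt, the integral truncated
#' at the first zero crossing of the autocorrelation (default) or estimated
#' by an exponential fit to the initial decay.
#'
#' @param series list of `list(z, time, force)` (see [gen_force_series()]),
#'   one per position.
#' @param T_K temperature (K), default 298.
#' @param cutoff `"zero_crossing"` or `"exp_fit"`.
#' @return A `diffusion_profile` data.frame: `z` (nm), `D` (nm^2/ps),
#'   `acf_integral` (kJ^2 mol^-2 nm^-2 ps), `cutoff_time` (ps).
#' @export
diffusion_from_force_autocorrelation <- function(series, T_K = 298,
                                                 cutoff = c("zero_crossing",
                                                            "exp_fit")) {
  cutoff <- match.arg(cutoff)
  RT <- ox_kT(T_K)
  rows <- lapply(series, function(s) {
    f <- s$force - mean(s$force)
    n <- length(f)
    dt <- s$time[2] - s$time[1]
    nlag <- min(n - 1L, max(200L, n %/% 10L))
    ac <- acov_fft(f, nlag)
    if (ac[1] <= 0) ox_stop("degenerate force series at z = ", s$z,
                            ": zero variance")
    zc <- which(ac <= 0)[1]
    if (cutoff == "zero_crossing") {
      if (is.na(zc)) {
        ox_stop("autocorrelation at z = ", s$z,
                " has no zero crossing within ", nlag, " lags")
      }
      if (zc <= 3L) {
        ox_stop("under-resolved force series at z = ", s$z,
                ": autocorrelation decays within ~", zc, " samples")
      }
      keep <- seq_len(zc - 1L)
      integral <- dt * (sum(ac[keep]) - ac[1] / 2)  # trapezoid from t = 0
    } else {
      m <- min(if (is.na(zc)) nlag else zc - 1L, nlag)
      if (m <= 3L) ox_stop("under-resolved force series at z = ", s$z)
      tt <- (seq_len(m) - 1L) * dt
      lac <- log(ac[seq_len(m)] / ac[1])
      tau_hat <- -1 / stats::coef(stats::lm(lac ~ tt + 0))[1]
      integral <- ac[1] * tau_hat
      zc <- m + 1L
    }
    if (integral <= 0) {
      ox_stop("non-positive autocorrelation integral at z = ", s$z)
    }
    data.frame(z = s$z, D = RT^2 / integral, acf_integral = integral,
               cutoff_time = (zc - 1L) * dt)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diffusion_profile", "data.frame")
  out
}

#' Membrane permeability from the inhomogeneous solubility-diffusion model
#'
#' P = 1 / integral exp(DeltaG(z)/RT) / D(z) dz over the membrane span,
#' by trapezoidal quadrature on the PMF grid (D interpolated onto it), with
#' the result converted to cm/s.
#'
#' @param pmf a `pmf_profile` (bulk-anchored).
#' @param dprof a `diffusion_profile`, or a single D value (nm^2/ps) used
#'   uniformly.
#' @param T_K temperature (K), default 298 (the permeability convention),
#'   even when trajectories were generated at body temperature; pass 310 to
#'   match the simulation thermostat.
#' @param bounds integration bounds (nm), default c(-4, 4), clipped to the
#'   sampled PMF range.
#' @return A `permeability_result`: `P_cm_s`, `integrand` (data.frame `z`,
#'   `R` = exp(G/RT)/D, ps/nm^2), `T_K`, `bounds`.
#' @export
permeability <- function(pmf, dprof, T_K = 298, bounds = c(-4, 4)) {
  stopifnot(inherits(pmf, "pmf_profile"))
  RT <- ox_kT(T_K)
  sel <- pmf$z >= bounds[1] & pmf$z <= bounds[2]
  if (sum(sel) < 2L) ox_stop("PMF grid does not cover the integration bounds")
  z <- pmf$z[sel]; G <- pmf$G[sel]
  D <- if (is.numeric(dprof) && is.null(dim(dprof)) && !is.data.frame(dprof)) {
    rep(dprof, length(z))
  } else {
    if (nrow(dprof) < 2L) ox_stop("diffusion profile needs >= 2 positions")
    if (min(dprof$z) > min(z) + 0.5 || max(dprof$z) < max(z) - 0.5) {
      ox_stop("diffusion profile does not cover the sampled PMF grid")
    }
    ## nearest-value extrapolation at the grid edges (D plateaus in bulk)
    stats::approx(dprof$z, dprof$D, xout = z, rule = 2)$y
  }
  if (any(!is.finite(D)) || any(D <= 0)) {
    ox_stop("D(z) must be finite and > 0 on the PMF grid")
  }
  R_z <- exp(G / RT) / D               # ps/nm^2
  integral <- sum(diff(z) * (utils::head(R_z, -1) + utils::tail(R_z, -1)) / 2)
  P <- (1 / integral) * ox_constants$NM_PS_TO_CM_S
  structure(list(P_cm_s = P, integrand = data.frame(z = z, R = R_z),
                 T_K = T_K, bounds = bounds, RT = RT),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("P = %.3g cm/s (T = %g K, bounds %.1f..%.1f nm)\n",
              x$P_cm_s, x$T_K, x$bounds[1], x$bounds[2]))
  invisible(x)
}
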