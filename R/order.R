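## Deuterium order parameter S_CD along acyl chains.
##
## S_CD(j) = < (3 cos^2 theta_j - 1) / 2 >, where theta_j is the angle
## between the skeletal C(j-1) -> C(j+1) axis and the membrane normal (z).
## The skeletal-vector definition is used deliberately (not the C-H-vector
## variant common in other tools).  S_CD = 1 means chains aligned with the
## normal, -0.5 perpendicular, 0 isotropic.  Terminal carbons have no
## skeletal axis and are excluded, not erroneous.

#' Group chain atoms by residue
#'
#' Builds the per-chain atom index lists [deuterium_order_parameter()]
#' consumes, from atoms named `<prefix><carbon index>` (e.g. C1, C2, ...),
#' one chain per residue id.
#'
#' @param obj an `md_frame` or `md_trajectory`.
#' @param prefix atom-name prefix of chain carbons, default `"C"`.
#' @param label chain label stored on each chain (default the residue name).
#' @return Named list of integer atom-index vectors in carbon order.
#' @export
chains_from_residues <- function(obj, prefix = "C", label = NULL) {
  a <- obj$atoms
  idx <- which(grepl(paste0("^", prefix, "[0-9]+$"), a$name))
  if (!length(idx)) ox_stop("no chain atoms with prefix '", prefix, "' found")
  carbon <- as.integer(sub(paste0("^", prefix), "", a$name[idx]))
  chains <- lapply(split(seq_along(idx), a$resid[idx]), function(k) {
    idx[k][order(carbon[k])]
  })
  names(chains) <- if (is.null(label)) {
    vapply(chains, function(ch) a$resname[ch[1]], "")
  } else rep(label, length(chains))
  chains
}

#' Deuterium order parameter profile
#'
#' @param obj an `md_frame` or `md_trajectory`.
#' @param chains list of integer atom-index vectors, each a chain in carbon
#'   order (see [chains_from_residues()]); chains of the same `names()` are
#'   pooled.
#' @return An `order_parameter_profile` data.frame with columns `chain`
#'   (label), `carbon` (index j), `scd` (mean), `sd`, `n`.
#' @export
deuterium_order_parameter <- function(obj, chains) {
  if (!length(chains)) ox_stop("no chains given")
  if (any(lengths(chains) < 3L)) ox_stop("chains must have >= 3 carbons")
  labels <- names(chains) %||% rep("chain", length(chains))
  coords_list <- if (inherits(obj, "md_trajectory")) {
    lapply(seq_len(n_frames(obj)), function(t) obj$coords[, , t])
  } else list(obj$coords)
  ## accumulate per (label, carbon)
  acc <- new.env(parent = emptyenv())
  for (coords in coords_list) {
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      nC <- length(ch)
      v <- coords[ch[3:nC], , drop = FALSE] - coords[ch[1:(nC - 2L)], , drop = FALSE]
      cos2 <- (v[, 3]^2) / rowSums(v^2)
      s <- (3 * cos2 - 1) / 2
      key <- labels[ci]
      cur <- acc[[key]] %||% list(sum = numeric(nC - 2L),
                                  sum2 = numeric(nC - 2L), n = 0L)
      cur$sum <- cur$sum + s
      cur$sum2 <- cur$sum2 + s^2
      cur$n <- cur$n + 1L
      acc[[key]] <- cur
    }
  }
  rows <- lapply(ls(acc), function(key) {
    cur <- acc[[key]]
    m <- cur$sum / cur$n
    varp <- pmax(cur$sum2 / cur$n - m^2, 0)
    data.frame(chain = key, carbon = seq_along(m) + 1L, scd = m,
               sd = sqrt(varp), n = cur$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("order_parameter_profile", "data.frame")
  out
}

#' Per-chain average order parameter
#'
#' Collapses an order-parameter profile to one average per chain label
#' (the per-species table semantics); optionally excludes the carbon
#' adjacent to the carbonyl (j = 2), since either convention appears in the
#' literature.
#'
#' @param profile an `order_parameter_profile`.
#' @param exclude_carbonyl_adjacent drop carbon j = 2 from the average?
#' @return data.frame with `chain`, `scd_mean`, `scd_sd` (across carbons).
#' @export
order_parameter_average <- function(profile, exclude_carbonyl_adjacent = FALSE) {
  d <- profile
  if (exclude_carbonyl_adjacent) d <- d[d$carbon > 2L, ]
  agg <- do.call(rbind, lapply(split(d, d$chain), function(g) {
    data.frame(chain = g$chain[1], scd_mean = mean(g$scd),
               scd_sd = stats::sd(g$scd))
  }))
  rownames(agg) <- NULL
  agg
}
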