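## Acyl-tail geometry: the nine-angle scheme describing tail orientation
## (alpha, delta: tilt against the leaflet normal), splay (beta), interior
## bending at a pivot carbon (gamma), plus the cholesterol ring-axis tilt
## (alpha3).  Alpha and delta are measured against the per-leaflet
## outward-to-inward normal, so 0 degrees means "pointing into the bilayer
## core" in both leaflets.  Gamma uses the interior-angle convention: a
## straight chain scores 180 degrees.  The two sn-2 variants (gamma2_1 /
## gamma2_2, delta2_1 / delta2_2) differ only in which mid-chain pivot
## carbon they use (first vs second oxidation-prone position, e.g. C9 vs C13
## for linoleate); the pivot atoms are supplied by the caller through the
## marker table.

#' Marker table for tail-geometry angles
#'
#' One row per lipid. Columns are atom indices into the frame (or NA when a
#' marker does not apply to the lipid class):
#' `P` (phosphate; O3 carbon for cholesterol), `sn1_CH3`, `sn2_CH3`
#' (terminal methyls), `sn1_COOH`, `sn2_COOH` (carbonyl carbons),
#' `pivot1`, `pivot2` (mid-chain pivot carbons of the sn-2 chain),
#' `chol_C17` (cholesterol ring junction). Plus `lipid` (id), `class`
#' (grouping label) and `leaflet`.
#'
#' @param lipid,class,leaflet id, grouping label and leaflet per lipid.
#' @param P,sn1_CH3,sn2_CH3,sn1_COOH,sn2_COOH,pivot1,pivot2,chol_C17 atom
#'   indices (NA allowed).
#' @return data.frame usable by [chain_angles()].
#' @export
angle_markers <- function(lipid, class, leaflet, P,
                          sn1_CH3 = NA, sn2_CH3 = NA,
                          sn1_COOH = NA, sn2_COOH = NA,
                          pivot1 = NA, pivot2 = NA, chol_C17 = NA) {
  n <- length(lipid)
  data.frame(lipid = lipid, class = class, leaflet = leaflet,
             P = as.integer(rep_len(P, n)),
             sn1_CH3 = as.integer(rep_len(sn1_CH3, n)),
             sn2_CH3 = as.integer(rep_len(sn2_CH3, n)),
             sn1_COOH = as.integer(rep_len(sn1_COOH, n)),
             sn2_COOH = as.integer(rep_len(sn2_COOH, n)),
             pivot1 = as.integer(rep_len(pivot1, n)),
             pivot2 = as.integer(rep_len(pivot2, n)),
             chol_C17 = as.integer(rep_len(chol_C17, n)))
}

## leaflet outward-to-inward normal (unit z component)
leaflet_normal_z <- function(leaflet) ifelse(leaflet == "outer", -1, 1)

angle_one_frame <- function(coords, mk) {
  nz <- leaflet_normal_z(mk$leaflet)
  normal <- cbind(0, 0, nz)
  get <- function(col) coords[mk[[col]], , drop = FALSE]
  vec <- function(from, to) get(to) - get(from)
  res <- list()
  has <- function(...) Reduce(`&`, lapply(list(...), function(c_) !is.na(mk[[c_]])))

  ok <- has("P", "sn1_CH3")
  if (any(ok)) res$alpha1 <- data.frame(i = which(ok),
    value = vec_angle_deg(vec("P", "sn1_CH3")[ok, , drop = FALSE],
                          normal[ok, , drop = FALSE]))
  ok <- has("P", "sn2_CH3")
  if (any(ok)) res$alpha2 <- data.frame(i = which(ok),
    value = vec_angle_deg(vec("P", "sn2_CH3")[ok, , drop = FALSE],
                          normal[ok, , drop = FALSE]))
  ok <- has("P", "chol_C17")
  if (any(ok)) res$alpha3 <- data.frame(i = which(ok),
    value = vec_angle_deg(vec("P", "chol_C17")[ok, , drop = FALSE],
                          normal[ok, , drop = FALSE]))
  ok <- has("P", "sn1_CH3") & has("P", "sn2_CH3")
  if (any(ok)) res$beta <- data.frame(i = which(ok),
    value = vec_angle_deg(vec("P", "sn1_CH3")[ok, , drop = FALSE],
                          vec("P", "sn2_CH3")[ok, , drop = FALSE]))
  ok <- has("P", "sn1_COOH", "sn1_CH3")
  if (any(ok)) res$gamma1 <- data.frame(i = which(ok),
    value = vec_angle_deg(vec("sn1_COOH", "P")[ok, , drop = FALSE],
                          vec("sn1_COOH", "sn1_CH3")[ok, , drop = FALSE]))
  ok <- has("sn2_COOH", "pivot1", "sn2_CH3")
  if (any(ok)) res$gamma2_1 <- data.frame(i = which(ok),
    value = vec_angle_deg(vec("pivot1", "sn2_COOH")[ok, , drop = FALSE],
                          vec("pivot1", "sn2_CH3")[ok, , drop = FALSE]))
  ok <- has("sn2_COOH", "pivot2", "sn2_CH3")
  if (any(ok)) res$gamma2_2 <- data.frame(i = which(ok),
    value = vec_angle_deg(vec("pivot2", "sn2_COOH")[ok, , drop = FALSE],
                          vec("pivot2", "sn2_CH3")[ok, , drop = FALSE]))
  ok <- has("P", "sn1_COOH")
  if (any(ok)) res$delta1 <- data.frame(i = which(ok),
    value = vec_angle_deg(vec("P", "sn1_COOH")[ok, , drop = FALSE],
                          normal[ok, , drop = FALSE]))
  ok <- has("P", "pivot1")
  if (any(ok)) res$delta2_1 <- data.frame(i = which(ok),
    value = vec_angle_deg(vec("P", "pivot1")[ok, , drop = FALSE],
                          normal[ok, , drop = FALSE]))
  ok <- has("P", "pivot2")
  if (any(ok)) res$delta2_2 <- data.frame(i = which(ok),
    value = vec_angle_deg(vec("P", "pivot2")[ok, , drop = FALSE],
                          normal[ok, , drop = FALSE]))
  res
}

#' Tail-geometry angle statistics
#'
#' Computes the angle set (alpha1, alpha2, alpha3, beta, gamma1, gamma2_1,
#' gamma2_2, delta1, delta2_1, delta2_2) per lipid class and leaflet, over
#' all frames. Lipids whose required markers are missing are skipped per
#' angle; an error is raised if more than half the lipids lack a phosphate
#' marker.
#'
#' @param obj an `md_frame` or `md_trajectory`.
#' @param markers marker table from [angle_markers()].
#' @return An `angle_set` data.frame with columns `class`, `leaflet`,
#'   `angle`, `mean`, `sd`, `n`. The raw per-observation values are attached
#'   as `attr(, "samples")`.
#' @export
chain_angles <- function(obj, markers) {
  if (mean(is.na(markers$P)) > 0.5) {
    ox_stop("more than 50% of lipids lack a phosphate/O3 marker")
  }
  coords_list <- if (inherits(obj, "md_trajectory")) {
    lapply(seq_len(n_frames(obj)), function(t) obj$coords[, , t])
  } else list(obj$coords)
  samples <- list()
  for (coords in coords_list) {
    per <- angle_one_frame(coords, markers)
    for (angle in names(per)) {
      d <- per[[angle]]
      samples[[length(samples) + 1L]] <-
        data.frame(class = markers$class[d$i], leaflet = markers$leaflet[d$i],
                   angle = angle, value = d$value)
    }
  }
  if (!length(samples)) ox_stop("no computable angles for the given markers")
  all_s <- do.call(rbind, samples)
  key <- interaction(all_s$class, all_s$leaflet, all_s$angle, drop = TRUE)
  agg <- do.call(rbind, lapply(split(all_s, key), function(g) {
    data.frame(class = g$class[1], leaflet = g$leaflet[1], angle = g$angle[1],
               mean = mean(g$value),
               sd = if (nrow(g) > 1L) stats::sd(g$value) else NA_real_,
               n = nrow(g))
  }))
  rownames(agg) <- NULL
  attr(agg, "samples") <- all_s
  class(agg) <- c("angle_set", "data.frame")
  agg
}
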