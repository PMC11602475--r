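## Geometric hydrogen-bond detection and per-hydroperoxide bonding rates.
## A donor-H ... acceptor triplet is a bond when the donor-acceptor distance
## (minimum image) is within the cutoff and the H-D...A angle (vertex at the
## donor, between D->H and D->A) is within the angular cutoff.  The default
## criteria (D-A <= 0.35 nm, H-D...A <= 30 degrees) are the de-facto
## standard geometric definition in MD tooling; both knobs are exposed.

#' Hydrogen-bond detection criteria
#'
#' @param max_DA_distance donor-acceptor distance cutoff (nm), > 0.
#' @param max_HDA_angle H-D...A angle cutoff (degrees), in (0, 90].
#' @return An `hbond_criteria` object.
#' @export
hbond_criteria <- function(max_DA_distance = 0.35, max_HDA_angle = 30) {
  if (max_DA_distance <= 0) ox_stop("max_DA_distance must be > 0")
  if (max_HDA_angle <= 0 || max_HDA_angle > 90) {
    ox_stop("max_HDA_angle must be in (0, 90] degrees")
  }
  structure(list(max_DA_distance = max_DA_distance,
                 max_HDA_angle = max_HDA_angle),
            class = "hbond_criteria")
}

## minimum-image displacement vectors (orthorhombic box)
min_image <- function(dvec, box) {
  for (k in 1:3) dvec[, k] <- dvec[, k] - box[k] * round(dvec[, k] / box[k])
  dvec
}

#' Detect hydrogen bonds in a frame
#'
#' @param frame an `md_frame`.
#' @param donors data.frame with columns `D` and `H` (atom indices); every
#'   donor must carry an explicit hydrogen.
#' @param acceptors integer vector of acceptor atom indices.
#' @param criteria an [hbond_criteria()] object.
#' @return data.frame of bonds with columns `D`, `H`, `A`, `distance` (nm),
#'   `angle` (degrees); zero rows when nothing bonds.
#' @export
detect_hbonds <- function(frame, donors, acceptors,
                          criteria = hbond_criteria()) {
  stopifnot(inherits(frame, "md_frame"))
  if (!all(c("D", "H") %in% names(donors))) {
    ox_stop("donors must have columns D and H")
  }
  if (any(is.na(donors$H))) {
    ox_stop("donor(s) without explicit H: atoms ",
            paste(donors$D[is.na(donors$H)], collapse = ", "))
  }
  nd <- nrow(donors); na_ <- length(acceptors)
  empty <- data.frame(D = integer(), H = integer(), A = integer(),
                      distance = numeric(), angle = numeric())
  if (nd == 0L || na_ == 0L) return(empty)
  xyz <- frame$coords; box <- frame$box
  out <- vector("list", nd)
  for (i in seq_len(nd)) {
    Di <- donors$D[i]; Hi <- donors$H[i]
    dv <- min_image(sweep(xyz[acceptors, , drop = FALSE], 2, xyz[Di, ]), box)
    dist <- sqrt(rowSums(dv^2))
    cand <- which(dist <= criteria$max_DA_distance & acceptors != Di)
    if (!length(cand)) next
    hv <- min_image(matrix(xyz[Hi, ] - xyz[Di, ], 1), box)
    ang <- vec_angle_deg(matrix(hv, length(cand), 3, byrow = TRUE),
                         dv[cand, , drop = FALSE])
    keep <- ang <= criteria$max_HDA_angle
    if (any(keep)) {
      out[[i]] <- data.frame(D = Di, H = Hi, A = acceptors[cand[keep]],
                             distance = dist[cand[keep]], angle = ang[keep])
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-group hydrogen-bond rates over a trajectory
#'
#' Counts bonds per frame between each hydroperoxide (or other donor) group
#' and each acceptor partner class, averages over frames, and normalizes per
#' group instance, producing rate tables in the bonds-per-frame-per-group
#' convention.
#'
#' @param traj an `md_trajectory`.
#' @param groups named list; each element is a list with `donors`
#'   (data.frame `D`, `H`) and `n_instances` (number of group copies the
#'   rate is normalized by; default the number of donor rows).
#' @param partner_classes named list of acceptor atom-index vectors;
#'   classes are expected to be disjoint.
#' @param criteria an [hbond_criteria()] object.
#' @return An `hbond_rate_table` data.frame: `group`, `partner`, `rate`
#'   (mean bonds per frame per group instance), `n_instances`, `n_frames`.
#'   Groups with zero instances yield a zero-rate row flagged by
#'   `n_instances = 0`.
#' @export
hbond_rates <- function(traj, groups, partner_classes,
                        criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "md_trajectory"))
  nt <- n_frames(traj)
  cls_atoms <- unlist(partner_classes, use.names = FALSE)
  if (anyDuplicated(cls_atoms)) {
    warning("partner classes overlap; rates will double-count", call. = FALSE)
  }
  rows <- list()
  for (g in names(groups)) {
    grp <- groups[[g]]
    n_inst <- grp$n_instances %||% nrow(grp$donors)
    for (p in names(partner_classes)) {
      total <- 0
      if (n_inst > 0L && nrow(grp$donors) > 0L) {
        for (t in seq_len(nt)) {
          b <- detect_hbonds(traj_frame(traj, t), grp$donors,
                             partner_classes[[p]], criteria)
          total <- total + nrow(b)
        }
      }
      rate <- if (n_inst > 0L) total / nt / n_inst else 0
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, partner = p, rate = rate,
                   n_instances = n_inst, n_frames = nt)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hbond_rate_table", "data.frame")
  out
}
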