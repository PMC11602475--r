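## Membrane composition construction and hydroperoxide substitution.
##
## A composition is a per-leaflet inventory of species counts.  The packaged
## default table is a reconstruction of the red-blood-cell membrane models:
## 200 phospholipids + 100 cholesterol (50/50 across leaflets, a 0.5
## cholesterol:phospholipid molar ratio), 157 lipids in the inner and 143 in
## the outer leaflet, with phosphatidylinositol folded into PS.  It is fully
## user-overridable through the `table` argument of
## [build_native_composition()].

#' Path to the packaged default native composition table
#' @return File path of the TSV table (columns leaflet, species, count).
#' @export
default_composition_path <- function() {
  system.file("extdata", "native_composition.tsv", package = "oxbilayer",
              mustWork = TRUE)
}

#' Read a composition table
#'
#' @param path delimited text file with columns `leaflet`, `species`, `count`.
#'   Tab- or comma-separated, detected from the header line.
#' @return data.frame with the three columns.
#' @export
read_composition_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("leaflet", "species", "count")
  if (!all(need %in% names(tab))) {
    ox_stop("composition table must have columns: ", paste(need, collapse = ", "))
  }
  tab[, need]
}

validate_composition_table <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    ox_stop("composition table is empty")
  }
  need <- c("leaflet", "species", "count")
  if (!all(need %in% names(table))) {
    ox_stop("composition table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(table$leaflet %in% c("inner", "outer"))) {
    bad <- setdiff(unique(table$leaflet), c("inner", "outer"))
    ox_stop("unknown leaflet label(s): ", paste(bad, collapse = ", "))
  }
  reg <- species_registry()
  unknown <- setdiff(unique(table$species), names(reg))
  if (length(unknown)) {
    ox_stop("unknown species code(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.numeric(table$count) || any(table$count != round(table$count))) {
    ox_stop("species counts must be integers")
  }
  if (any(table$count <= 0)) ox_stop("species counts must be > 0")
  table$count <- as.integer(table$count)
  ## collapse duplicate (leaflet, species) rows
  agg <- stats::aggregate(count ~ leaflet + species, data = table, FUN = sum)
  agg <- agg[order(match(agg$leaflet, c("inner", "outer")), agg$species), ]
  rownames(agg) <- NULL
  agg
}

new_membrane_composition <- function(table, label) {
  structure(list(table = table, label = label),
            class = "membrane_composition")
}

#' Build the native membrane composition
#'
#' Assembles a per-leaflet species inventory from a composition table. With
#' the packaged default table the result has 200 phospholipids and 100
#' cholesterol molecules, 157 lipids in the inner leaflet and 143 in the
#' outer, and a cholesterol:phospholipid molar ratio of 0.5.
#'
#' @param table a data.frame with columns `leaflet`, `species`, `count`, or a
#'   path to such a TSV/CSV file. Defaults to the packaged table.
#' @return A `membrane_composition` object with `label = "native"`.
#' @export
build_native_composition <- function(table = default_composition_path()) {
  if (is.character(table)) table <- read_composition_table(table)
  tab <- validate_composition_table(table)
  new_membrane_composition(tab, "native")
}

#' @export
print.membrane_composition <- function(x, ...) {
  cnt <- composition_counts(x)
  cat(sprintf("membrane_composition (%s): %d lipids (%d phospholipids, %d cholesterol)\n",
              x$label, cnt$total_lipids, cnt$phospholipids, cnt$cholesterol))
  cat(sprintf("  inner: %d lipids | outer: %d lipids | chol:PL = %.3f | charge = %+d\n",
              cnt$inner_lipids, cnt$outer_lipids, cnt$chol_pl_ratio,
              cnt$total_charge))
  invisible(x)
}

## Headline counts used by print(), summaries and the audits.
composition_counts <- function(comp) {
  tab <- comp$table
  reg <- species_registry()
  is_chol <- tab$species == "CHOL"
  chol <- sum(tab$count[is_chol])
  pl <- sum(tab$count[!is_chol])
  charge <- sum(vapply(seq_len(nrow(tab)), function(i) {
    reg[[tab$species[i]]]$formal_charge * tab$count[i]
  }, numeric(1)))
  list(
    total_lipids = sum(tab$count),
    phospholipids = pl,
    cholesterol = chol,
    inner_lipids = sum(tab$count[tab$leaflet == "inner"]),
    outer_lipids = sum(tab$count[tab$leaflet == "outer"]),
    inner_phospholipids = sum(tab$count[tab$leaflet == "inner" & !is_chol]),
    outer_phospholipids = sum(tab$count[tab$leaflet == "outer" & !is_chol]),
    chol_pl_ratio = chol / pl,
    total_charge = as.integer(charge)
  )
}

#' Default hydroperoxide substitution rules
#'
#' Species whose single PUFA chain sits at sn-2 (or on the sphingomyelin
#' N-acyl position) are split between the two positional hydroperoxide
#' isomers; species with PUFA chains at both positions map to the single
#' double-hydroperoxide species with the distal isomer at sn-1 and the
#' proximal isomer at sn-2 (13/9, 15/12, 17/14).
#'
#' @param fractionA fraction of each single-PUFA population assigned to the
#'   proximal isomer (9-, 12-, 14-OOH); default 0.5.
#' @param rounding_policy `"half_up_A"` (deterministic: round half up for the
#'   proximal isomer, remainder to the distal) or `"random"` (seeded coin
#'   flip for the odd molecule).
#' @return A `substitution_rules` object.
#' @export
substitution_rules <- function(fractionA = 0.5,
                               rounding_policy = c("half_up_A", "random")) {
  stopifnot(fractionA >= 0, fractionA <= 1)
  rounding_policy <- match.arg(rounding_policy)
  single <- lapply(.ox_isomers, function(iso) {
    list(isomerA = iso$proximal$pos, isomerB = iso$distal$pos,
         fractionA = fractionA)
  })
  double <- lapply(.ox_isomers, function(iso) {
    list(sn1 = iso$distal$pos, sn2 = iso$proximal$pos)
  })
  structure(list(single_pufa_split = single, double_pufa_assignment = double,
                 rounding_policy = rounding_policy),
            class = "substitution_rules")
}

#' Derive the ferroptosis composition by hydroperoxide substitution
#'
#' Replaces every PUFA-containing phospholipid of a native composition with
#' its hydroperoxide derivative(s): single-PUFA species are split between the
#' two positional isomers per the rules, double-PUFA species map to the
#' corresponding sn1/sn2 isomer pair. Non-PUFA species are untouched; the
#' total and per-leaflet lipid counts are conserved.
#'
#' @param native a `membrane_composition` with `label = "native"`.
#' @param rules a [substitution_rules()] object.
#' @param seed integer seed (used only when `rounding_policy = "random"`).
#' @return A `membrane_composition` with `label = "ferroptosis"`.
#' @export
apply_ferroptosis_substitution <- function(native, rules = substitution_rules(),
                                           seed = 1L) {
  stopifnot(inherits(native, "membrane_composition"))
  if (!identical(native$label, "native")) {
    ox_stop("substitution expects a composition with label 'native'")
  }
  stopifnot(inherits(rules, "substitution_rules"))
  reg <- species_registry()
  rows <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(native$table))) {
      leaflet <- native$table$leaflet[i]
      name <- native$table$species[i]
      count <- native$table$count[i]
      sp <- reg[[name]]
      if (!species_is_pufa(sp)) {
        rows[[length(rows) + 1L]] <- data.frame(leaflet = leaflet,
                                                species = name, count = count)
        next
      }
      fam <- species_pufa_family(sp)
      both <- chain_is_pufa(sp$sn1) && chain_is_pufa(sp$sn2)
      if (both) {
        asg <- rules$double_pufa_assignment[[fam]]
        if (is.null(asg)) ox_stop("substitution rules do not cover double-PUFA species ", name)
        nm <- paste0(name, asg$sn2, ",", asg$sn1)
        if (is.null(reg[[nm]])) ox_stop("no oxidized species defined for ", name)
        rows[[length(rows) + 1L]] <- data.frame(leaflet = leaflet,
                                                species = nm, count = count)
      } else {
        spl <- rules$single_pufa_split[[fam]]
        if (is.null(spl)) ox_stop("substitution rules do not cover PUFA species ", name)
        nA <- count * spl$fractionA
        if (nA != round(nA)) {
          nA <- switch(rules$rounding_policy,
                       half_up_A = floor(nA + 0.5),
                       random    = floor(nA) + stats::rbinom(1L, 1L, 0.5))
        }
        nA <- as.integer(nA); nB <- count - nA
        nmA <- paste0(name, spl$isomerA); nmB <- paste0(name, spl$isomerB)
        if (is.null(reg[[nmA]]) || is.null(reg[[nmB]])) {
          ox_stop("no oxidized species defined for ", name)
        }
        if (nA > 0L) rows[[length(rows) + 1L]] <-
            data.frame(leaflet = leaflet, species = nmA, count = nA)
        if (nB > 0L) rows[[length(rows) + 1L]] <-
            data.frame(leaflet = leaflet, species = nmB, count = nB)
      }
    }
  })
  tab <- validate_composition_table(do.call(rbind, rows))
  new_membrane_composition(tab, "ferroptosis")
}

## Display label for a hydroperoxide class, e.g. "9HPODE" or "13HPODE/9HPODE".
hpd_class_label <- function(sp) {
  suffix <- c(LA = "HPODE", AA = "HPETE", DHA = "HPDHA")
  fam <- species_pufa_family(sp)
  p1 <- sp$sn1$ooh_positions %||% integer()
  p2 <- sp$sn2$ooh_positions %||% integer()
  if (length(p1) && length(p2)) {
    paste0(p1, suffix[[fam]], "/", p2, suffix[[fam]])
  } else {
    paste0(c(p1, p2), suffix[[fam]])
  }
}

#' Audit tables for a membrane composition
#'
#' @param comp a `membrane_composition`.
#' @return A list of data.frames and scalars:
#'   `per_leaflet` (per-leaflet species counts and mole fractions),
#'   `whole` (whole-membrane species mole fractions),
#'   `headgroup` (per-leaflet headgroup-class mole fractions),
#'   `oxidation` (counts and mol% of total phospholipid by oxidation state),
#'   `hpd_classes` (counts and mol% of total phospholipid per hydroperoxide
#'   class, oxidized compositions only), and `counts` (headline totals,
#'   cholesterol:phospholipid ratio, total formal charge).
#' @export
composition_summary <- function(comp) {
  stopifnot(inherits(comp, "membrane_composition"))
  tab <- comp$table
  reg <- species_registry()
  cnt <- composition_counts(comp)

  per_leaflet <- do.call(rbind, lapply(split(tab, tab$leaflet), function(d) {
    d$mole_fraction <- d$count / sum(d$count)
    d
  }))
  rownames(per_leaflet) <- NULL

  whole <- stats::aggregate(count ~ species, data = tab, FUN = sum)
  whole$mole_fraction <- whole$count / sum(whole$count)

  tab$headgroup <- vapply(tab$species, function(s) reg[[s]]$headgroup_class, "")
  headgroup <- stats::aggregate(count ~ leaflet + headgroup, data = tab, FUN = sum)
  headgroup$mole_fraction <- stats::ave(headgroup$count, headgroup$leaflet,
                                        FUN = function(x) x / sum(x))

  pl <- tab[tab$species != "CHOL", ]
  pl$oxidation <- vapply(pl$species, function(s) species_oxidation(reg[[s]]), "")
  oxidation <- stats::aggregate(count ~ oxidation, data = pl, FUN = sum)
  oxidation$mol_pct_phospholipid <- 100 * oxidation$count / cnt$phospholipids

  oxi <- pl[pl$oxidation != "native", ]
  hpd_classes <- NULL
  if (nrow(oxi)) {
    oxi$hpd_class <- vapply(oxi$species, function(s) hpd_class_label(reg[[s]]), "")
    hpd_classes <- stats::aggregate(count ~ hpd_class, data = oxi, FUN = sum)
    hpd_classes$mol_pct_phospholipid <- 100 * hpd_classes$count / cnt$phospholipids
  }

  list(per_leaflet = per_leaflet, whole = whole, headgroup = headgroup,
       oxidation = oxidation, hpd_classes = hpd_classes, counts = cnt)
}

#' Write a composition audit to CSV and JSON
#'
#' @param comp a `membrane_composition`.
#' @param prefix output path prefix; writes `<prefix>_per_leaflet.csv`,
#'   `<prefix>_summary.json`.
#' @return Invisibly, the paths written.
#' @export
write_composition_audit <- function(comp, prefix) {
  s <- composition_summary(comp)
  csv <- paste0(prefix, "_per_leaflet.csv")
  utils::write.csv(s$per_leaflet, csv, row.names = FALSE)
  js <- paste0(prefix, "_summary.json")
  jsonlite::write_json(
    list(label = comp$label, counts = s$counts,
         oxidation = s$oxidation, hpd_classes = s$hpd_classes),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(c(csv, js))
}

#' Rebuild a composition from its per-leaflet audit table
#'
#' Round-trip companion of [composition_summary()]: the `per_leaflet` audit
#' table contains the full inventory, so the composition can be rebuilt
#' exactly.
#'
#' @param per_leaflet the `per_leaflet` data.frame from [composition_summary()].
#' @param label composition label.
#' @return A `membrane_composition`.
#' @export
composition_from_summary <- function(per_leaflet, label = "native") {
  tab <- validate_composition_table(per_leaflet[, c("leaflet", "species", "count")])
  new_membrane_composition(tab, label)
}
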