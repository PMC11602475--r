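## Lipid species vocabulary for the erythrocyte membrane models.
##
## Acyl chains are identified by the classic one-letter codes used in mixed
## phospholipid nomenclature (P = palmitoyl 16:0, S = stearoyl 18:0,
## O = oleoyl 18:1(9Z), L = linoleoyl 18:2(9Z,12Z), A = arachidonoyl
## 20:4(5Z,8Z,11Z,14Z), D = docosahexaenoyl 22:6(4Z,7Z,10Z,13Z,16Z,19Z)),
## except for a few irregular legacy names (DSPS = distearoyl-PS,
## SOPS = stearoyl-oleoyl-PS) which are hard-coded.  Hydroperoxide (OOH)
## derivatives carry the oxidized-carbon index as a suffix (e.g. PLPE9 has
## 9-OOH linoleate at sn-2) and the accompanying cis->trans double-bond
## rearrangement.

#' Construct an acyl-chain specification
#'
#' @param carbon_count number of carbons in the chain.
#' @param double_bonds data.frame with columns `position` (integer, index of
#'   the first carbon of the double bond) and `geometry` (`"cis"` or
#'   `"trans"`), or `NULL` for a saturated chain.
#' @param ooh_positions integer vector of carbon indices bearing a
#'   hydroperoxide (-OOH) group; empty for non-oxidized chains.
#' @return An object of class `chain_spec`.
#' @export
chain_spec <- function(carbon_count, double_bonds = NULL, ooh_positions = integer()) {
  stopifnot(is.numeric(carbon_count), carbon_count >= 2)
  carbon_count <- as.integer(carbon_count)
  if (is.null(double_bonds)) {
    double_bonds <- data.frame(position = integer(), geometry = character())
  }
  stopifnot(all(c("position", "geometry") %in% names(double_bonds)))
  if (nrow(double_bonds)) {
    if (any(double_bonds$position < 1L | double_bonds$position > carbon_count)) {
      ox_stop("double-bond positions must lie in 1..carbon_count")
    }
    if (is.unsorted(double_bonds$position, strictly = TRUE)) {
      ox_stop("double-bond positions must be strictly increasing")
    }
    if (!all(double_bonds$geometry %in% c("cis", "trans"))) {
      ox_stop("double-bond geometry must be 'cis' or 'trans'")
    }
  }
  ooh_positions <- as.integer(ooh_positions)
  if (length(ooh_positions) &&
      any(ooh_positions < 1L | ooh_positions > carbon_count)) {
    ox_stop("ooh_positions must lie in 1..carbon_count")
  }
  structure(list(carbon_count = carbon_count,
                 double_bonds = double_bonds,
                 ooh_positions = ooh_positions),
            class = "chain_spec")
}

cis_bonds <- function(...) {
  pos <- c(...)
  data.frame(position = as.integer(pos), geometry = rep("cis", length(pos)))
}

bond_tab <- function(positions, geometries) {
  data.frame(position = as.integer(positions), geometry = geometries)
}

## Base (non-oxidized) chain library.
.ox_chains <- local({
  list(
    P   = chain_spec(16),
    S   = chain_spec(18),
    O   = chain_spec(18, cis_bonds(9)),
    L   = chain_spec(18, cis_bonds(9, 12)),
    A   = chain_spec(20, cis_bonds(5, 8, 11, 14)),
    D   = chain_spec(22, cis_bonds(4, 7, 10, 13, 16, 19)),
    LIG = chain_spec(24),                 # lignoceroyl 24:0
    BEH = chain_spec(22),                 # behenoyl 22:0
    NER = chain_spec(24, cis_bonds(15)),  # nervonoyl 24:1(15Z)
    ## Hydroperoxide derivatives (primary trans-cis isomers).
    L9  = chain_spec(18, bond_tab(c(10, 12), c("trans", "cis")), 9L),
    L13 = chain_spec(18, bond_tab(c(9, 11), c("cis", "trans")), 13L),
    A12 = chain_spec(20, bond_tab(c(5, 8, 10, 14), c("cis", "cis", "trans", "cis")), 12L),
    A15 = chain_spec(20, bond_tab(c(5, 8, 11, 13), c("cis", "cis", "cis", "trans")), 15L),
    D14 = chain_spec(22, bond_tab(c(4, 7, 10, 12, 16, 19),
                                  c("cis", "cis", "cis", "trans", "cis", "cis")), 14L),
    D17 = chain_spec(22, bond_tab(c(4, 7, 10, 13, 15, 19),
                                  c("cis", "cis", "cis", "cis", "trans", "cis")), 17L)
  )
})

## Number of double bonds; a chain is a PUFA when it has >= 2.
chain_is_pufa <- function(chain) {
  !is.null(chain) && nrow(chain$double_bonds) >= 2L
}

## PUFA family of a base chain code: "LA", "AA", "DHA" or NA.
pufa_family <- function(code) {
  switch(code, L = "LA", A = "AA", D = "DHA",
         L9 = "LA", L13 = "LA", A12 = "AA", A15 = "AA",
         D14 = "DHA", D17 = "DHA", NA_character_)
}

## Proximal/distal OOH carbon per PUFA family, and the oxidized chain codes.
.ox_isomers <- list(
  LA  = list(proximal = list(pos = 9L,  code = "L9"),
             distal   = list(pos = 13L, code = "L13")),
  AA  = list(proximal = list(pos = 12L, code = "A12"),
             distal   = list(pos = 15L, code = "A15")),
  DHA = list(proximal = list(pos = 14L, code = "D14"),
             distal   = list(pos = 17L, code = "D17"))
)

#' Construct a lipid species
#'
#' @param name short species code (e.g. `"PLPE"`, `"CHOL"`, `"DLPE9,13"`).
#' @param headgroup_class one of `"PC"`, `"PE"`, `"PS"`, `"SM"`, `"CHOL"`.
#' @param sn1,sn2 [chain_spec()] objects or `NULL`. Sphingomyelins carry their
#'   single acyl chain in `sn2` with `sphingoid = TRUE`; cholesterol has no
#'   chains.
#' @param formal_charge integer formal charge (PS species are -1).
#' @param sphingoid logical, `TRUE` for sphingomyelin backbones.
#' @param parent native species code this species derives from (oxidized
#'   species only), else `NA`.
#' @return An object of class `lipid_species`.
#' @export
lipid_species <- function(name, headgroup_class, sn1 = NULL, sn2 = NULL,
                          formal_charge = 0L, sphingoid = FALSE, parent = NA_character_) {
  headgroup_class <- match.arg(headgroup_class, c("PC", "PE", "PS", "SM", "CHOL"))
  if (headgroup_class == "CHOL" && (!is.null(sn1) || !is.null(sn2))) {
    ox_stop("cholesterol carries no acyl chains")
  }
  if (headgroup_class == "PS" && formal_charge != -1L) {
    ox_stop("PS species carry formal charge -1")
  }
  if (headgroup_class == "SM" && !sphingoid) {
    ox_stop("SM species must set sphingoid = TRUE")
  }
  structure(list(name = name, headgroup_class = headgroup_class,
                 sn1 = sn1, sn2 = sn2,
                 formal_charge = as.integer(formal_charge),
                 sphingoid = isTRUE(sphingoid), parent = parent),
            class = "lipid_species")
}

## Native species definitions: name -> (class, sn1 code, sn2 code).
.ox_native_defs <- list(
  ## PE
  PLPE = c("PE", "P", "L"),  SLPE = c("PE", "S", "L"),  DLPE = c("PE", "L", "L"),
  SAPE = c("PE", "S", "A"),  DAPE = c("PE", "A", "A"),  SDPE = c("PE", "S", "D"),
  ODPE = c("PE", "O", "D"),  DDPE = c("PE", "D", "D"),  POPE = c("PE", "P", "O"),
  DPPE = c("PE", "P", "P"),
  ## PC
  PLPC = c("PC", "P", "L"),  SLPC = c("PC", "S", "L"),  OLPC = c("PC", "O", "L"),
  DLPC = c("PC", "L", "L"),  SAPC = c("PC", "S", "A"),  DAPC = c("PC", "A", "A"),
  SDPC = c("PC", "S", "D"),  POPC = c("PC", "P", "O"),  DPPC = c("PC", "P", "P"),
  ## PS (charge -1)
  SLPS = c("PS", "S", "L"),  SAPS = c("PS", "S", "A"),  DAPS = c("PS", "A", "A"),
  SDPS = c("PS", "S", "D"),  DDPS = c("PS", "D", "D"),  DSPS = c("PS", "S", "S"),
  SOPS = c("PS", "S", "O"),
  ## SM (single N-acyl chain, stored as sn2)
  PSM  = c("SM", NA, "P"),   SSM  = c("SM", NA, "S"),   LNSM = c("SM", NA, "L"),
  LSM  = c("SM", NA, "LIG"), BSM  = c("SM", NA, "BEH"), DSM  = c("SM", NA, "D"),
  NSM  = c("SM", NA, "NER")
)

build_native_species <- function() {
  out <- list()
  for (nm in names(.ox_native_defs)) {
    def <- .ox_native_defs[[nm]]
    cls <- def[1]
    sn1 <- if (is.na(def[2])) NULL else .ox_chains[[def[2]]]
    sn2 <- if (is.na(def[3])) NULL else .ox_chains[[def[3]]]
    out[[nm]] <- lipid_species(nm, cls, sn1, sn2,
                               formal_charge = if (cls == "PS") -1L else 0L,
                               sphingoid = cls == "SM")
  }
  out$CHOL <- lipid_species("CHOL", "CHOL")
  out
}

## Derive oxidized species from each PUFA-bearing native species.
build_oxidized_species <- function(native) {
  out <- list()
  for (sp in native) {
    if (sp$headgroup_class == "CHOL") next
    p1 <- if (!is.null(sp$sn1) && chain_is_pufa(sp$sn1)) pufa_family(chain_code(sp$sn1)) else NA
    p2 <- if (!is.null(sp$sn2) && chain_is_pufa(sp$sn2)) pufa_family(chain_code(sp$sn2)) else NA
    if (is.na(p1) && is.na(p2)) next
    if (!is.na(p1) && !is.na(p2)) {
      ## double-PUFA: sn1 distal isomer, sn2 proximal isomer
      iso <- .ox_isomers[[p2]]
      nm <- paste0(sp$name, iso$proximal$pos, ",", iso$distal$pos)
      out[[nm]] <- lipid_species(nm, sp$headgroup_class,
                                 .ox_chains[[iso$distal$code]],
                                 .ox_chains[[iso$proximal$code]],
                                 formal_charge = sp$formal_charge,
                                 sphingoid = sp$sphingoid, parent = sp$name)
    } else {
      ## single PUFA at sn-2 (or the SM acyl chain)
      fam <- p2
      iso <- .ox_isomers[[fam]]
      for (which in c("proximal", "distal")) {
        nm <- paste0(sp$name, iso[[which]]$pos)
        out[[nm]] <- lipid_species(nm, sp$headgroup_class, sp$sn1,
                                   .ox_chains[[iso[[which]]$code]],
                                   formal_charge = sp$formal_charge,
                                   sphingoid = sp$sphingoid, parent = sp$name)
      }
    }
  }
  out
}

## Recover the library code of a chain_spec by identity of its fields.
chain_code <- function(chain) {
  if (is.null(chain)) return(NA_character_)
  for (nm in names(.ox_chains)) {
    ch <- .ox_chains[[nm]]
    if (ch$carbon_count == chain$carbon_count &&
        identical(ch$ooh_positions, chain$ooh_positions) &&
        nrow(ch$double_bonds) == nrow(chain$double_bonds) &&
        all(ch$double_bonds$position == chain$double_bonds$position) &&
        all(ch$double_bonds$geometry == chain$double_bonds$geometry)) {
      return(nm)
    }
  }
  NA_character_
}

.ox_registry_env <- new.env(parent = emptyenv())

#' Lipid species registry
#'
#' Returns the full species vocabulary: every native erythrocyte-membrane
#' species (Tables of mixed-chain PC/PE/PS/SM plus cholesterol) together with
#' all derivable hydroperoxide species. Phosphatidylinositol is deliberately
#' absent: the membrane models replace it with PS.
#'
#' @return Named list of [lipid_species()] objects.
#' @export
species_registry <- function() {
  if (is.null(.ox_registry_env$registry)) {
    native <- build_native_species()
    .ox_registry_env$registry <- c(native, build_oxidized_species(native))
  }
  .ox_registry_env$registry
}

## Oxidation state of a species: "native", "single-OOH" or "double-OOH".
species_oxidation <- function(sp) {
  n_ooh <- length(sp$sn1$ooh_positions %||% integer()) +
    length(sp$sn2$ooh_positions %||% integer())
  if (n_ooh == 0L) "native" else if (n_ooh == 1L) "single-OOH" else "double-OOH"
}

## PUFA family of the species' chains ("LA", "AA", "DHA") or NA.
species_pufa_family <- function(sp) {
  fams <- c(
    if (!is.null(sp$sn1)) pufa_family(chain_code(sp$sn1)),
    if (!is.null(sp$sn2)) pufa_family(chain_code(sp$sn2))
  )
  fams <- fams[!is.na(fams)]
  if (length(fams)) fams[length(fams)] else NA_character_
}

## TRUE when the (native) species contains at least one PUFA chain.
species_is_pufa <- function(sp) {
  chain_is_pufa(sp$sn1) || chain_is_pufa(sp$sn2)
}
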