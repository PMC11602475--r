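test_that("default native composition reproduces the model's headline counts", {
  nat <- build_native_composition()
  cnt <- composition_summary(nat)$counts
  expect_identical(cnt$phospholipids, 200L)
  expect_identical(cnt$cholesterol, 100L)
  expect_identical(cnt$inner_lipids, 157L)
  expect_identical(cnt$outer_lipids, 143L)
  expect_equal(cnt$chol_pl_ratio, 0.5)
})

test_that("composition validation rejects degenerate and malformed tables", {
  expect_error(build_native_composition(data.frame()), "empty")
  expect_error(build_native_composition(
    data.frame(leaflet = "inner", species = "XXPC", count = 5)),
    "unknown species")
  expect_error(build_native_composition(
    data.frame(leaflet = "inner", species = "POPC", count = 2.5)),
    "integer")
  expect_error(build_native_composition(
    data.frame(leaflet = "middle", species = "POPC", count = 2)),
    "leaflet")
})

test_that("hydroperoxide substitution splits single-PUFA species 50/50", {
  nat <- build_native_composition(data.frame(
    leaflet = "inner", species = c("PLPE", "POPC"), count = c(8, 4)))
  fer <- apply_ferroptosis_substitution(nat)
  tab <- fer$table
  expect_identical(tab$count[tab$species == "PLPE9"], 4L)
  expect_identical(tab$count[tab$species == "PLPE13"], 4L)
  expect_identical(tab$count[tab$species == "POPC"], 4L)
  expect_false("PLPE" %in% tab$species)
})

test_that("substitution conserves counts, leaflets and charge", {
  nat <- build_native_composition()
  fer <- apply_ferroptosis_substitution(nat)
  c_nat <- composition_summary(nat)$counts
  c_fer <- composition_summary(fer)$counts
  expect_identical(c_fer$total_lipids, c_nat$total_lipids)
  expect_identical(c_fer$inner_lipids, c_nat$inner_lipids)
  expect_identical(c_fer$outer_lipids, c_nat$outer_lipids)
  expect_identical(c_fer$total_charge, c_nat$total_charge)
  ## charge bookkeeping: -1 per PS instance
  reg <- species_registry()
  n_ps <- sum(nat$table$count[vapply(nat$table$species, function(s)
    reg[[s]]$headgroup_class == "PS", TRUE)])
  expect_identical(c_nat$total_charge, -n_ps)
})

test_that("ferroptosis hydroperoxide classes land on the printed mole fractions", {
  fer <- apply_ferroptosis_substitution(build_native_composition())
  s <- composition_summary(fer)
  pct <- stats::setNames(s$hpd_classes$mol_pct_phospholipid, s$hpd_classes$hpd_class)
  ## printed values with the documented +/- 0.3 mol% reconstruction band
  expect_lt(abs(pct[["9HPODE"]] - 4.3), 0.31)
  expect_lt(abs(pct[["13HPODE"]] - 4.6), 0.31)
  expect_lt(abs(pct[["12HPETE"]] - 5.6), 0.31)
  expect_lt(abs(pct[["15HPETE"]] - 5.6), 0.31)
  expect_lt(abs(pct[["14HPDHA"]] - 4.0), 0.31)
  expect_lt(abs(pct[["17HPDHA"]] - 4.0), 0.31)
  expect_lt(abs(pct[["13HPODE/9HPODE"]] - 1.6), 0.31)
  expect_lt(abs(pct[["15HPETE/12HPETE"]] - 2.3), 0.31)
  expect_lt(abs(pct[["17HPDHA/14HPDHA"]] - 1.6), 0.31)
})

test_that("oxidized classes conserve the native PUFA-phospholipid fraction", {
  nat <- build_native_composition()
  fer <- apply_ferroptosis_substitution(nat)
  reg <- species_registry()
  pufa_nat <- sum(nat$table$count[vapply(nat$table$species, function(s)
    s != "CHOL" && oxbilayer:::species_is_pufa(reg[[s]]), TRUE)])
  ox <- composition_summary(fer)$oxidation
  oxidized <- sum(ox$count[ox$oxidation != "native"])
  expect_identical(oxidized, pufa_nat)
})

test_that("per-leaflet mole fractions normalize and the summary round-trips", {
  for (comp in list(build_native_composition(),
                    apply_ferroptosis_substitution(build_native_composition()))) {
    s <- composition_summary(comp)
    fr <- tapply(s$per_leaflet$mole_fraction, s$per_leaflet$leaflet, sum)
    expect_equal(as.numeric(fr), c(1, 1), tolerance = 1e-12)
    rebuilt <- composition_from_summary(s$per_leaflet, comp$label)
    expect_equal(rebuilt$table, comp$table)
  }
})

test_that("odd single-PUFA counts follow the rounding policy deterministically", {
  nat <- build_native_composition(data.frame(
    leaflet = "inner", species = "PLPE", count = 7))
  fer <- apply_ferroptosis_substitution(nat)  # half-up to proximal isomer
  expect_identical(fer$table$count[fer$table$species == "PLPE9"], 4L)
  expect_identical(fer$table$count[fer$table$species == "PLPE13"], 3L)
  ## random policy is seed-reproducible
  r1 <- apply_ferroptosis_substitution(nat, substitution_rules(rounding_policy = "random"),
                                       seed = 11L)
  r2 <- apply_ferroptosis_substitution(nat, substitution_rules(rounding_policy = "random"),
                                       seed = 11L)
  expect_equal(r1$table, r2$table)
})

test_that("double-PUFA species map to the distal-sn1/proximal-sn2 isomer pair", {
  nat <- build_native_composition(data.frame(
    leaflet = "inner", species = c("DLPE", "DAPE", "DDPE"), count = c(2, 2, 2)))
  fer <- apply_ferroptosis_substitution(nat)
  expect_setequal(fer$table$species, c("DLPE9,13", "DAPE12,15", "DDPE14,17"))
  reg <- species_registry()
  sp <- reg[["DLPE9,13"]]
  expect_identical(sp$sn1$ooh_positions, 13L)
  expect_identical(sp$sn2$ooh_positions, 9L)
})

test_that("toy coordinate placement honors tolerance, counts and determinism", {
  comp <- build_native_composition(data.frame(
    leaflet = c("inner", "inner", "outer", "outer"),
    species = c("POPC", "CHOL", "POPC", "PSM"),
    count = c(1, 1, 1, 1)))
  fr <- place_toy_coordinates(comp, box = c(30, 30, 10), tolerance = 0.2, seed = 5)
  d <- as.matrix(stats::dist(fr$coords)); diag(d) <- Inf
  expect_gte(min(d), 0.2)
  expect_identical(length(unique(fr$atoms$resid)), 4L)
  fr2 <- place_toy_coordinates(comp, box = c(30, 30, 10), tolerance = 0.2, seed = 5)
  expect_identical(fr$coords, fr2$coords)
  ## infeasible packing in a tiny box
  big <- build_native_composition()
  expect_error(place_toy_coordinates(big, box = c(1, 1, 10), tolerance = 0.2),
               "infeasible")
})
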