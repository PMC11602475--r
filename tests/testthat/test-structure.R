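test_that("a single atom lands its mass in one density bin", {
  atoms <- make_atoms(1L, "X", "P", 10)
  ## membrane COM = the atom itself, so it sits at z' = 0
  traj <- md_trajectory(atoms, array(c(1, 1, 2.525), dim = c(1, 3, 1)),
                        times = 0, box = c(2, 2, 5))
  dp <- mass_density_profile(traj, list(p = 1L), bin_width = 0.05)
  expect_equal(sum(dp$density > 0), 1L)
  expect_equal(max(dp$density),
               10 / (0.05 * 2 * 2) * ox_constants$AMU_PER_NM3_TO_KG_M3)
})

test_that("density profiles are additive and mass-conserving on synthetic bilayers", {
  comp <- flat_comp(40)
  lb <- gen_layered_bilayer(comp, n_frames = 20, n_waters = 500,
                            box = c(8, 8, 12), seed = 11)
  tr <- lb$trajectory
  sels <- list(phosphate = select_atoms(tr, resname = "phosphate"),
               carbonyl = select_atoms(tr, resname = "carbonyl"),
               methyl = select_atoms(tr, resname = "methyl"),
               water = select_atoms(tr, resname = "SOL"))
  all_idx <- sort(unlist(sels))
  dp <- mass_density_profile(tr, c(sels, list(all = all_idx)))
  ## additivity: component profiles sum to the whole-selection profile
  expect_equal(rowSums(dp$density[, names(sels)]), dp$density[, "all"],
               tolerance = 1e-10)
  ## integral over z times box area recovers the selected mass to <= 0.1%
  total_mass <- sum(tr$atoms$mass[all_idx])
  integral <- sum(dp$density[, "all"]) * dp$bin_width * dp$box_area /
    ox_constants$AMU_PER_NM3_TO_KG_M3
  expect_lt(abs(integral - total_mass) / total_mass, 1e-3)
})

test_that("mirrored bilayers give symmetric phosphate profiles", {
  comp <- flat_comp(60)
  lb <- gen_layered_bilayer(comp, n_frames = 60, n_waters = 0,
                            box = c(10, 10, 12), seed = 12)
  dp <- mass_density_profile(lb$trajectory,
                             list(p = select_atoms(lb$trajectory, resname = "phosphate")))
  y <- dp$density[, 1]
  ## compare each half's integrated mass
  lhs <- sum(y[dp$bin_centers < 0]); rhs <- sum(y[dp$bin_centers > 0])
  expect_lt(abs(lhs - rhs) / (lhs + rhs), 0.05)
})

test_that("phosphate-peak thickness recovers the generator truth", {
  comp <- flat_comp(60)
  for (case in list(list(mean = 2.26, expect = 4.52),
                    list(mean = 2.10, expect = 4.20))) {
    lb <- gen_layered_bilayer(comp, layers = list(
      phosphate = list(mean = case$mean, sigma = 0.15, mass = 94.97, name = "P")),
      n_frames = 80, n_waters = 0, box = c(10, 10, 12), seed = 13)
    dp <- mass_density_profile(lb$trajectory,
                               list(phosphate = select_atoms(lb$trajectory,
                                                             resname = "phosphate")))
    th <- membrane_thickness(dp)
    expect_lt(abs(th$thickness - case$expect), dp$bin_width)
    expect_equal(th$thickness, th$leaflet_inner + th$leaflet_outer)
  }
})

test_that("single-leaflet profiles are rejected by the thickness estimator", {
  ## all phosphate mass in one plane: the COM-recentered profile has a peak
  ## on one side of z = 0 only
  atoms <- make_atoms(1:10, "phosphate", "P", 95, leaflet = "outer")
  coords <- array(0, dim = c(10, 3, 1))
  coords[, 3, 1] <- 8
  traj <- md_trajectory(atoms, coords, 0, c(5, 5, 12))
  dp <- mass_density_profile(traj, list(phosphate = 1:10))
  expect_error(membrane_thickness(dp), "half-profile")
})

test_that("water zone counts match uniform-slab expectations", {
  comp <- flat_comp(30)
  lb <- gen_layered_bilayer(comp, n_frames = 40, n_waters = 3000,
                            water_exclusion_halfwidth = 2.0,
                            box = c(8, 8, 12), seed = 14)
  wz <- water_zone_counts(lb$trajectory, zone_width = 0.4, n_zones = 8)
  ## zones 1-4 lie strictly inside the exclusion slab: no waters (zone 5
  ## touches the slab edge, where membrane-COM jitter can leak a count)
  expect_equal(max(wz[, 1:4]), 0)
  ## zone 7 covers |z| in (2.4, 2.8]: width 2 x 0.4 nm of the 8 nm water column
  expected <- 3000 * 0.8 / 8
  se <- sqrt(expected)
  expect_lt(abs(mean(wz[, 7]) - expected), 3 * se / sqrt(nrow(wz)))
  ## conservation bound
  expect_true(all(rowSums(wz) <= 3000))
  expect_error(water_zone_counts(lb$trajectory, zone_width = -1), "> 0")
})

test_that("area per lipid follows the box arithmetic", {
  comp <- build_native_composition(data.frame(
    leaflet = c("outer", "outer"), species = c("POPC", "CHOL"),
    count = c(100, 20)))
  atoms <- make_atoms(1L, "POPC", "P", 31)
  traj <- md_trajectory(atoms, array(1, dim = c(1, 3, 3)), times = 0:2,
                        box = matrix(8, 3, 3))
  a <- area_per_lipid(traj, comp, "outer")
  expect_equal(a$mean, 0.64)
  expect_equal(stats::var(a$apl), 0)
  a2 <- area_per_lipid(traj, comp, "outer", include_cholesterol = TRUE)
  expect_equal(a2$mean / a$mean, 100 / 120)
  expect_error(area_per_lipid(traj, comp, "inner"), "zero lipids")
})

test_that("order parameters hit the analytic tilt values and stay in bounds", {
  for (tilt in c(0, 30, 54.7, 90)) {
    g <- gen_ordered_chains(8, 10, tilt_deg = tilt, seed = 21)
    prof <- deuterium_order_parameter(g$frame, chains_from_residues(g$frame))
    expected <- (3 * cos(tilt * pi / 180)^2 - 1) / 2
    expect_equal(prof$scd, rep(expected, nrow(prof)), tolerance = 1e-12)
    expect_true(all(prof$scd >= -0.5 - 1e-12 & prof$scd <= 1 + 1e-12))
  }
})

test_that("isotropic chains average to zero order within Monte-Carlo error", {
  g <- gen_ordered_chains(4000, 8, tilt_deg = "isotropic", seed = 22)
  prof <- deuterium_order_parameter(g$frame, chains_from_residues(g$frame))
  se <- prof$sd / sqrt(prof$n)
  expect_true(all(abs(prof$scd) <= 3 * se))
})

test_that("per-chain averages expose both carbonyl-adjacent conventions", {
  g <- gen_ordered_chains(5, 8, tilt_deg = 30, seed = 23)
  prof <- deuterium_order_parameter(g$frame, chains_from_residues(g$frame))
  a1 <- order_parameter_average(prof)
  a2 <- order_parameter_average(prof, exclude_carbonyl_adjacent = TRUE)
  expect_equal(a1$scd_mean, a2$scd_mean, tolerance = 1e-12)  # uniform tilt
  expect_identical(nrow(a1), 1L)
})

test_that("collinear tail geometry yields the defining angle values", {
  ## outer-leaflet lipid pointing straight down (into the core): P on top,
  ## carbonyl below, terminal methyl at the bottom
  coords <- rbind(c(0, 0, 3), c(0, 0, 2.4), c(0, 0, 2.4), c(0, 0, 1),
                  c(0, 0, 1))
  atoms <- make_atoms(rep(1L, 5), "LIP", c("P", "C1A", "C1B", "CA3", "CB3"), 12)
  fr <- md_frame(coords, c(10, 10, 10), 0, atoms)
  mk <- angle_markers(lipid = 1L, class = "LA", leaflet = "outer", P = 1L,
                      sn1_CH3 = 4L, sn2_CH3 = 5L, sn1_COOH = 2L, sn2_COOH = 3L)
  as_ <- chain_angles(fr, mk)
  val <- function(a) as_$mean[as_$angle == a]
  expect_equal(val("alpha1"), 0, tolerance = 1e-9)
  expect_equal(val("delta1"), 0, tolerance = 1e-9)
  expect_equal(val("gamma1"), 180, tolerance = 1e-9)
  expect_equal(val("beta"), 0, tolerance = 1e-9)
})

test_that("planar symmetric chains give the constructed splay angle", {
  ## sn1 and sn2 methyls 15 degrees either side of the inward normal
  th <- 15 * pi / 180
  coords <- rbind(c(0, 0, 5),
                  c(sin(th), 0, 5 - cos(th)),
                  c(-sin(th), 0, 5 - cos(th)))
  atoms <- make_atoms(rep(1L, 3), "LIP", c("P", "CA3", "CB3"), 12)
  fr <- md_frame(coords, c(10, 10, 10), 0, atoms)
  mk <- angle_markers(1L, "LA", "outer", P = 1L, sn1_CH3 = 2L, sn2_CH3 = 3L)
  as_ <- chain_angles(fr, mk)
  expect_equal(as_$mean[as_$angle == "beta"], 30, tolerance = 1e-9)
  expect_equal(as_$mean[as_$angle == "alpha1"], 15, tolerance = 1e-9)
})

test_that("imposed tilt ensembles are recovered by the alpha estimator", {
  set.seed(31)
  n <- 400
  tilt <- 25 * pi / 180
  phi <- stats::runif(n, 0, 2 * pi)
  P <- cbind(stats::runif(n, 0, 20), stats::runif(n, 0, 20), 5)
  tips <- P + 1.8 * cbind(sin(tilt) * cos(phi), sin(tilt) * sin(phi),
                          -cos(tilt))
  coords <- rbind(P, tips)
  atoms <- make_atoms(c(seq_len(n), seq_len(n)), "LIP",
                      rep(c("P", "CA3"), each = n), 12)
  fr <- md_frame(coords, c(20, 20, 10), 0, atoms)
  mk <- angle_markers(seq_len(n), "LA", "outer", P = seq_len(n),
                      sn1_CH3 = n + seq_len(n))
  as_ <- chain_angles(fr, mk)
  row <- as_[as_$angle == "alpha1", ]
  expect_lt(abs(row$mean - 25), 3 * row$sd / sqrt(row$n) + 1e-9)
})

test_that("peak shifts are signed toward the center and antisymmetric", {
  comp <- flat_comp(60)
  mk_prof <- function(mean, seed) {
    lb <- gen_layered_bilayer(comp, layers = list(
      phosphate = list(mean = mean, sigma = 0.12, mass = 95, name = "P")),
      n_frames = 60, n_waters = 0, box = c(10, 10, 12), seed = seed)
    mass_density_profile(lb$trajectory,
                         list(phosphate = select_atoms(lb$trajectory,
                                                       resname = "phosphate")))
  }
  pA <- mk_prof(2.26, 41)
  pB <- mk_prof(2.06, 42)
  expect_equal(unname(profile_peak_shift(pA, pA, "phosphate")), c(0, 0))
  sh <- profile_peak_shift(pA, pB, "phosphate")
  expect_lt(abs(sh[["inner"]] - 0.2), pA$bin_width)
  expect_lt(abs(sh[["outer"]] - 0.2), pA$bin_width)
  expect_equal(unname(profile_peak_shift(pB, pA, "phosphate")),
               -unname(sh), tolerance = 1e-12)
  expect_error(profile_peak_shift(pA, pB, "cholesterol"), "no component")
})
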