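test_that("GRO files parse with nm units and survive a round trip", {
  gro <- tempfile(fileext = ".gro")
  writeLines(c("test t= 12.0", "    3",
               "    1SOL     OW    1   1.000   2.000   3.000",
               "    1SOL    HW1    2   1.100   2.000   3.000",
               "    2POP      P    3   4.000   4.500   0.250",
               "   5.00000   5.00000   5.00000"), gro)
  fr <- read_coordinates(gro)
  expect_identical(nrow(fr$coords), 3L)
  expect_equal(fr$box, c(5, 5, 5))
  expect_equal(fr$time, 12)
  expect_equal(fr$coords[1, ], c(1, 2, 3))
  expect_identical(fr$atoms$name[3], "P")
  ## round trip
  out <- tempfile(fileext = ".gro")
  write_coordinates(fr, out)
  fr2 <- read_coordinates(out)
  expect_equal(fr2$coords, fr$coords, tolerance = 1e-3)
  expect_equal(fr2$box, fr$box)
})

test_that("malformed and truncated coordinate files fail with line context", {
  gro <- tempfile(fileext = ".gro")
  writeLines(c("title", "    3",
               "    1SOL     OW    1   1.000   2.000   3.000"), gro)
  expect_error(read_coordinates(gro), "truncated")
  bad <- tempfile(fileext = ".gro")
  writeLines(c("title", "    1",
               "    1SOL     OW    1   x.xxx   2.000   3.000",
               "   5.0 5.0 5.0"), bad)
  expect_error(read_coordinates(bad), "line 3")
  tric <- tempfile(fileext = ".gro")
  writeLines(c("title", "    1",
               "    1SOL     OW    1   1.000   2.000   3.000",
               "   5.0 5.0 5.0 0.0 0.0 1.2 0.0 0.0 0.0"), tric)
  expect_error(read_coordinates(tric), "triclinic")
})

test_that("PDB coordinates convert from angstroms to nm", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1           1",
    sprintf("%-6s%5d %-4s %-4s%5d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            "ATOM", 1L, " C1", "POP", 1L, 10.0, 0.0, 5.0, 1, 0),
    "END"), pdb)
  fr <- read_coordinates(pdb)
  expect_equal(fr$coords[1, 1], 1.0, tolerance = 1e-6)
  expect_equal(fr$box, c(5, 5, 5))
})

test_that("DCD trajectories round-trip and match the bio3d reader", {
  comp <- flat_comp(10)
  bm <- gen_brownian_membrane(comp, 2, n_frames = 8, dt = 100, seed = 3)
  td <- tempfile(); dir.create(td)
  topo <- file.path(td, "topo.gro")
  write_coordinates(traj_frame(bm$trajectory, 1), topo)
  dcd <- file.path(td, "traj.dcd")
  write_dcd(bm$trajectory, dcd)
  tr <- read_trajectory(topo, dcd)
  expect_equal(tr$coords, bm$trajectory$coords, tolerance = 1e-5)
  expect_identical(tr$times, bm$trajectory$times)
  expect_equal(tr$box, bm$trajectory$box, tolerance = 1e-5)
  ## independent reader cross-check of the codec
  bd <- bio3d::read.dcd(dcd, verbose = FALSE)
  for (i in c(1L, 8L)) {
    expect_equal(matrix(bd[i, ], ncol = 3, byrow = TRUE) / 10,
                 bm$trajectory$coords[, , i], tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("trajectory reading rejects mismatches, empties and XTC", {
  comp <- flat_comp(5)
  bm <- gen_brownian_membrane(comp, 2, n_frames = 4, dt = 10, seed = 4)
  td <- tempfile(); dir.create(td)
  dcd <- file.path(td, "t.dcd")
  write_dcd(bm$trajectory, dcd)
  ## topology with a different atom count
  other <- gen_brownian_membrane(flat_comp(3), 2, n_frames = 2, dt = 10, seed = 4)
  topo_bad <- file.path(td, "bad.gro")
  write_coordinates(traj_frame(other$trajectory, 1), topo_bad)
  expect_error(read_trajectory(topo_bad, dcd), "atom-count mismatch.*6.*10|atom-count mismatch.*10")
  topo <- file.path(td, "ok.gro")
  write_coordinates(traj_frame(bm$trajectory, 1), topo)
  expect_error(read_trajectory(topo, dcd, format = "XTC"), "not supported")
  ## truncated binary
  raw <- readBin(dcd, "raw", file.size(dcd))
  trunc <- file.path(td, "trunc.dcd")
  writeBin(raw[1:(length(raw) - 200L)], trunc)
  expect_error(read_trajectory(topo, trunc), "truncated|corrupt")
})

test_that("pullx window series round-trip with sidecar metadata", {
  ws <- list(window_series(1.2, 100, time = 1:100, z = rnorm(100, 1.2, 0.1)),
             window_series(1.0, 100, time = 1:100, z = rnorm(100, 1.0, 0.1)),
             window_series(0.8, 100, time = 1:100, z = rnorm(100, 0.8, 0.1)))
  td <- tempfile(); dir.create(td)
  paths <- write_window_series(ws, td)
  back <- read_window_series(paths)
  expect_length(back, 3L)
  expect_length(back[[1]]$z, 100L)
  expect_equal(back[[2]]$z, ws[[2]]$z, tolerance = 1e-6)
  expect_equal(back[[3]]$center, 0.8)
  expect_equal(back[[1]]$force_constant, 100)
  ## comment lines are skipped (the writer emits #/@ headers)
  expect_true(any(grepl("^[#@]", readLines(paths[1]))))
  ## missing sidecar is an error
  file.remove(paste0(paths[2], ".json"))
  expect_error(read_window_series(paths[2]), "sidecar")
  ## non-numeric payload names file and line
  bad <- file.path(td, "bad.xvg")
  writeLines(c("# hdr", "1.0 abc"), bad)
  jsonlite::write_json(list(center = 0, force_constant = 10),
                       paste0(bad, ".json"), auto_unbox = TRUE)
  expect_error(read_window_series(bad), "line 2")
})

test_that("leaflet tags survive coordinate serialization via the sidecar", {
  comp <- build_native_composition(data.frame(
    leaflet = c("inner", "outer"), species = c("POPE", "SLPC"), count = c(2, 2)))
  fr <- place_toy_coordinates(comp, box = c(20, 20, 10), seed = 2)
  for (ext in c(".gro", ".pdb")) {
    p <- tempfile(fileext = ext)
    write_coordinates(fr, p)
    back <- read_coordinates(p)
    expect_identical(back$atoms$leaflet, fr$atoms$leaflet)
    expect_identical(back$atoms$species, fr$atoms$species)
  }
})
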