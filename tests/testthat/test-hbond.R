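test_that("the geometric criteria decide individual triplets", {
  coords <- rbind(c(1, 1, 1),          # donor
                  c(1.098, 1, 1.009),  # H roughly toward the acceptor (~5 deg)
                  c(1.25, 1, 1),       # acceptor at 0.25 nm
                  c(1, 1, 2),          # far acceptor (0.50 nm... below)
                  c(1.5, 1, 1))
  atoms <- make_atoms(1:5, "X", c("OD", "HD", "OA", "OA", "OA"),
                      c(16, 1, 16, 16, 16))
  fr <- md_frame(coords, c(5, 5, 5), 0, atoms)
  donors <- data.frame(D = 1L, H = 2L)
  b <- detect_hbonds(fr, donors, acceptors = 3L)
  expect_identical(nrow(b), 1L)
  expect_lt(b$angle, 30)
  ## 0.5 nm acceptor is outside the distance cutoff
  expect_identical(nrow(detect_hbonds(fr, donors, acceptors = 5L)), 0L)
  expect_error(detect_hbonds(fr, data.frame(D = 1L, H = NA), 3L), "without explicit H")
})

test_that("vectorized detection equals the brute-force oracle on random frames", {
  crit <- hbond_criteria()
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    coords <- cbind(runif(3 * n, 0, 2.2), runif(3 * n, 0, 2.2),
                    runif(3 * n, 0, 2.2))
    atoms <- make_atoms(seq_len(3 * n), "X",
                        rep(c("OD", "HD", "OA"), n),
                        rep(c(16, 1, 16), n))
    fr <- md_frame(coords, c(2.2, 2.2, 2.2), 0, atoms)
    donors <- data.frame(D = seq_len(n) * 3 - 2, H = seq_len(n) * 3 - 1)
    acceptors <- seq_len(n) * 3
    fast <- nrow(detect_hbonds(fr, donors, acceptors, crit))
    slow <- hbond_bruteforce(fr, donors, acceptors, crit)
    expect_identical(fast, slow)
  }
})

test_that("planted fixtures are detected exactly, including margins", {
  for (kb in c(0, 3, 9)) {
    fx <- gen_hbond_fixture(kb, 6, seed = kb + 1)
    b <- detect_hbonds(fx$frame, fx$donors, fx$acceptors)
    expect_identical(nrow(b), as.integer(kb))
    expect_identical(hbond_bruteforce(fx$frame, fx$donors, fx$acceptors,
                                      hbond_criteria()), as.integer(kb))
  }
})

test_that("detection is invariant under rigid rotation and translation", {
  fx <- gen_hbond_fixture(6, 6, seed = 9)
  fr <- fx$frame
  n0 <- nrow(detect_hbonds(fr, fx$donors, fx$acceptors))
  ## rotate about z by 30 degrees around the box center, then wrap
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  ctr <- fr$box / 2
  rot <- sweep(sweep(fr$coords, 2, ctr) %*% t(R), 2, ctr, `+`)
  rot <- sweep(rot, 2, fr$box, function(x, b) x %% b)
  fr2 <- md_frame(rot, fr$box, 0, fr$atoms)
  expect_identical(nrow(detect_hbonds(fr2, fx$donors, fx$acceptors)), n0)
  ## translate across the periodic boundary
  fr3 <- md_frame(sweep(fr$coords + 0.77 * fr$box[1], 2, fr$box,
                        function(x, b) x %% b), fr$box, 0, fr$atoms)
  expect_identical(nrow(detect_hbonds(fr3, fx$donors, fx$acceptors)), n0)
})

test_that("rates average per frame and per group instance", {
  ## one persistent bond (donor 1) and one never-bonded donor over 100 frames
  coords <- rbind(c(1, 1, 1), c(1.1, 1, 1), c(1.3, 1, 1),
                  c(3, 3, 3), c(3.1, 3, 3), c(4.2, 3, 3))
  atoms <- make_atoms(1:6, "X", c("OD", "HD", "OA", "OD", "HD", "OA"),
                      c(16, 1, 16, 16, 1, 16))
  arr <- array(rep(coords, 100), dim = c(6, 3, 100))
  arr <- aperm(array(rep(t(coords), 100), dim = c(3, 6, 100)), c(2, 1, 3))
  traj <- md_trajectory(atoms, arr, times = 0:99, box = c(6, 6, 6))
  rates <- hbond_rates(traj,
                       groups = list(g1 = list(donors = data.frame(D = 1L, H = 2L)),
                                     g2 = list(donors = data.frame(D = 4L, H = 5L))),
                       partner_classes = list(acc = c(3L, 6L)))
  expect_equal(rates$rate[rates$group == "g1"], 1.0)
  expect_equal(rates$rate[rates$group == "g2"], 0.0)
})

test_that("Bernoulli occupancy fixtures recover the occupancy probability", {
  ## bond present in a random 30% of frames: move the acceptor out of range
  set.seed(77)
  nt <- 400
  present <- stats::rbinom(nt, 1, 0.3) == 1
  arr <- array(0, dim = c(3, 3, nt))
  for (t in seq_len(nt)) {
    arr[1, , t] <- c(1, 1, 1)
    arr[2, , t] <- c(1.1, 1, 1)
    arr[3, , t] <- if (present[t]) c(1.3, 1, 1) else c(2.5, 1, 1)
  }
  atoms <- make_atoms(1:3, "X", c("OD", "HD", "OA"), c(16, 1, 16))
  traj <- md_trajectory(atoms, arr, times = seq_len(nt) - 1, box = c(6, 6, 6))
  rates <- hbond_rates(traj, list(g = list(donors = data.frame(D = 1L, H = 2L))),
                       list(acc = 3L))
  p_hat <- rates$rate
  se <- sqrt(0.3 * 0.7 / nt)
  expect_lt(abs(p_hat - mean(present)), 1e-12)  # exact per-frame counting
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("rates are additive over a partition of the acceptor set", {
  fx <- gen_hbond_fixture(8, 4, seed = 15)
  arr <- array(fx$frame$coords, dim = c(nrow(fx$frame$coords), 3, 2))
  traj <- md_trajectory(fx$frame$atoms, arr, times = 0:1, box = fx$frame$box)
  accs <- fx$acceptors
  split1 <- accs[seq_along(accs) %% 2 == 0]
  split2 <- accs[seq_along(accs) %% 2 == 1]
  rates <- suppressWarnings(  # "all" deliberately overlaps the partition
    hbond_rates(traj, list(g = list(donors = fx$donors)),
                list(a = split1, b = split2, all = accs)))
  r <- stats::setNames(rates$rate, rates$partner)
  expect_equal(r[["a"]] + r[["b"]], r[["all"]], tolerance = 1e-12)
})
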