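test_that("neutral transition rates follow the one-pulse formula and its limits", {
  # direct evaluation of the closed form
  nr <- neutral_rates(demography(1e5, 0.17, 430))
  expect_equal(unname(nr["L10"]), 356.5, tolerance = 2e-3)
  expect_equal(unname(nr["L01"]), unname(nr["L10"]) * 0.17 / 0.83)
  # t << 2Ne: L10 -> (1 - m) t per Morgan
  nr2 <- neutral_rates(demography(1e7, 0.25, 100))
  expect_equal(unname(nr2["L10"]), 0.75 * 100, tolerance = 1e-3)
  # m -> 0: L01 -> 0 while L10 -> 2Ne (1 - e^{-t/2Ne})
  nr3 <- neutral_rates(demography(1e4, 1e-9, 200))
  expect_equal(unname(nr3["L01"]), 0, tolerance = 1e-5)
  expect_equal(unname(nr3["L10"]), 2e4 * (1 - exp(-0.01)), tolerance = 1e-6)
})

test_that("selection off reduces both backends to the neutral rates", {
  dem <- demography(5000, 0.15, 150)
  nr <- neutral_rates(dem)
  fwd <- forward_transition_rates(dem, 0)
  expect_lt(max(abs(fwd$grid$f10 - nr[["L10"]])), 1e-8 * nr[["L10"]])
  expect_lt(max(abs(fwd$grid$f01 - nr[["L01"]])), 1e-6 * nr[["L10"]])
  fp <- four_point_fit(dem, 0)
  expect_equal(fp$params10$k, 0)
  r <- c(0, 1e-4, 0.01, 0.2)
  ev <- curve_eval(fp, r)
  expect_equal(ev$f10, rep(nr[["L10"]], 4))
  expect_equal(ev$f01, rep(nr[["L01"]], 4))
})

test_that("selection curves are monotone, direction-correct, and symmetric in r", {
  dem <- demography(1e4, 0.1, 200)
  nr <- neutral_rates(dem)
  for (backend in c("forward", "fourpoint")) {
    crv <- if (backend == "forward") forward_transition_rates(dem, 0.05)
           else four_point_fit(dem, 0.05)
    r <- seq(0, 4 * crv$r2, length.out = 200)
    ev <- curve_eval(crv, r)
    tol <- 1e-6 * nr[["L10"]]
    expect_false(is.unsorted(ev$f10 + tol))          # f10 grows to L10
    expect_false(is.unsorted(rev(ev$f01) - tol))     # f01 falls to L01
    expect_true(all(ev$f10 >= 0 & ev$f10 <= nr[["L10"]] + tol))
    expect_true(all(ev$f01 >= nr[["L01"]] - tol))
    expect_lt(ev$f10[1], 0.5 * nr[["L10"]])          # depressed near the sweep
    expect_gt(ev$f01[1], 2 * nr[["L01"]])            # elevated near the sweep
    # distance-only model: left and right of the focal site are identical
    evn <- curve_eval(crv, -r)
    expect_equal(evn$f10, ev$f10)
    expect_equal(evn$f01, ev$f01)
  }
})

test_that("stronger selection widens the dip in the donor-to-recipient rate", {
  dem <- demography(1e4, 0.1, 200)
  nr <- neutral_rates(dem)
  width <- vapply(c(0.01, 0.05, 0.1), function(s) {
    g <- forward_transition_rates(dem, s)$grid
    max(g$r[g$f10 < 0.9 * nr[["L10"]]])
  }, numeric(1))
  expect_false(is.unsorted(width))
  expect_gt(width[3], width[1])
})

test_that("the four-point curve reproduces its three anchors exactly", {
  dem <- demography(1e4, 0.1, 200)
  fp <- four_point_fit(dem, 0.05)
  traj <- logistic_trajectory(dem, 0.05)
  h <- fp$r1 / 20
  anch <- aiscan:::transition_hazards(dem, traj, c(0, fp$r1, fp$r2),
                                      rep(h, 3))
  ev <- curve_eval(fp, c(0, fp$r1, fp$r2))
  expect_equal(ev$f10, anch$f10, tolerance = 1e-10)
  expect_equal(ev$f01, anch$f01, tolerance = 1e-10)
})

test_that("empirical switch rates from tract simulations match the model curves", {
  # moderate sweep kept short of fixation so both directions stay informative
  dem <- demography(10000, 0.2, 60)
  s <- 0.05
  set.seed(99)
  pop <- simulate_admixture(dem, scenario(selected = data.frame(pos = 0.5, s = s)),
                            n_sample = 10000)
  grid <- seq(0.5, 0.58, by = 0.004)
  anc <- tract_ancestry(pop, grid)
  crv <- forward_transition_rates(dem, s, r_max = 0.1,
                                  traj = pop$trajectory[, 1])
  n <- length(grid)
  d <- 0.004
  emp10 <- emp01 <- mod10 <- mod01 <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    from1 <- anc[, i] == 1
    emp10[i] <- mean(anc[from1, i + 1] == 0)
    emp01[i] <- mean(anc[!from1, i + 1] == 1)
    uv <- aiscan:::interval_switch_probs(crv, (grid[i] + grid[i + 1]) / 2 - 0.5, d)
    mod10[i] <- uv$u
    mod01[i] <- uv$v
  }
  # one population replicate: chromosomes share a genealogy, so allow a
  # generous band on the mean switch probabilities
  expect_lt(mean(abs(emp10 - mod10)) / mean(mod10), 0.35)
  # recipient-to-donor switching is a local-equilibrium approximation;
  # check its load-bearing content: the implied marginal donor-frequency
  # profile matches the empirical one, and switching into donor is
  # elevated near the focal site
  ab <- aiscan:::hitchhike_ab(grid - 0.5, pop$trajectory[, 1])
  xt <- tail(pop$trajectory[, 1], 1)
  q_mod <- xt * ab$a + (1 - xt) * ab$b
  expect_lt(max(abs(colMeans(anc) - q_mod)), 0.08)
  expect_gt(mean(emp01[1:5]), mean(emp01[17:20]))
  # and donor switching is depressed near the focal site
  expect_lt(mean(emp10[1:5]), mean(emp10[16:20]))
})

test_that("dosage transition matrices are stochastic, identity at d = 0, and match two-chromosome enumeration", {
  Tm <- dosage_transition_matrix(2, 0.3, 0.1)
  expect_equal(rowSums(Tm), rep(1, 3))
  # brute force over two independent chromosomes
  P <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE) # rows: from 0, from 1
  states <- list(c(0, 0), c(0, 1), c(1, 1))
  brute <- matrix(0, 3, 3)
  for (i in 1:3) for (c1 in 0:1) for (c2 in 0:1) {
    pr <- P[states[[i]][1] + 1, c1 + 1] * P[states[[i]][2] + 1, c2 + 1]
    brute[i, c1 + c2 + 1] <- brute[i, c1 + c2 + 1] + pr
  }
  expect_equal(Tm, brute)
  # d = 0 gives the identity for every ploidy
  crv <- aiscan:::neutral_curve(demography(1e4, 0.2, 100))
  Ts <- site_transition_matrices(crv, c(0.1, 0.1), 0.05, ploidy = 3)
  expect_equal(Ts[[1]], diag(4))
})

test_that("the neutral single-chromosome chain is stationary at (1 - m, m)", {
  dem <- demography(1e4, 0.3, 150)
  crv <- aiscan:::neutral_curve(dem)
  Tm <- site_transition_matrices(crv, c(0, 0.02), 0, ploidy = 1)[[1]]
  pi0 <- c(0.7, 0.3)
  expect_equal(as.numeric(pi0 %*% Tm), pi0)
})
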