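# Reaction-diffusion solver, tissue construction, scenarios, activation.

test_that("half-saturation constant follows the kinetic identity", {
  expect_equal(compute_k(0.1, 0.01, 0.01), 0.2)
  expect_equal(compute_k(0.1, 0.5, 0), 5)  # k_deg = 0: dissociation constant
  expect_error(compute_k(0, 1, 1), "k_on")
  set.seed(1)
  for (i in 1:20) {
    kon <- runif(1, 1e-3, 1); koff <- runif(1, 0, 10); kdeg <- runif(1, 0, 10)
    p <- model_params(k_on = kon, k_off = koff, k_deg = kdeg)
    expect_identical(p$k, (kdeg + koff) / kon)
  }
})

test_that("cell placement is reproducible, non-overlapping and inside
          the domain", {
  par <- tiny_params()
  t1 <- place_cells(par, seed = 5)
  t2 <- place_cells(par, seed = 5)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 40)
  d2 <- as.matrix(dist(t1[c("x", "y")]))^2
  diag(d2) <- Inf
  expect_gte(sqrt(min(d2)), 2 * par$cell_radius + par$min_gap - 1e-9)
  expect_true(all(sqrt(t1$x^2 + t1$y^2) + t1$radius < par$domain_radius))
  expect_equal(sum(t1$population == "Treg"), round(0.2 * 40))
  expect_equal(nrow(place_cells(model_params(n_cells = 0), seed = 1)), 0)
  expect_error(place_cells(model_params(n_cells = 500, domain_radius = 50),
                           seed = 1), "density")
})

test_that("mean nearest-neighbour distance matches an independent
          dart-throwing oracle", {
  par <- tiny_params()
  nn_mean <- function(xy) {
    d <- as.matrix(dist(xy)); diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  pkg <- mean(vapply(1:5, function(s) {
    nn_mean(place_cells(par, seed = s)[c("x", "y")])
  }, 0))
  # independent re-implementation of uniform sequential adsorption
  oracle_one <- function(seed) {
    set.seed(seed * 1000 + 17)
    rmax <- par$domain_radius - par$cell_radius - par$dx
    dmin <- 2 * par$cell_radius + par$min_gap
    pts <- matrix(NA_real_, 0, 2)
    while (nrow(pts) < par$n_cells) {
      r <- rmax * sqrt(runif(1)); a <- runif(1, 0, 2 * pi)
      p <- c(r * cos(a), r * sin(a))
      if (nrow(pts) == 0 ||
          min(sqrt(colSums((t(pts) - p)^2))) >= dmin) pts <- rbind(pts, p)
    }
    nn_mean(pts)
  }
  oracle <- mean(vapply(1:5, oracle_one, 0))
  expect_lt(abs(pkg - oracle) / oracle, 0.15)
})

test_that("binary and graded role assignment preserve total secretion", {
  pr <- default_profiles()
  par <- model_params(n_cells = 400, treg_frac = 0, domain_radius = 260,
                      dx = 4, min_gap = 1)
  tis <- place_cells(par, seed = 2)
  # stimulus where the normalized producer weight is exactly 0.6:
  # w(A) = A(1+a50)/(A+a50) with a50 = 1/4  =>  A = 0.15/0.65
  A <- 0.15 / 0.65
  expect_equal(producer_weight(pr, A), 0.6, tolerance = 1e-12)
  bin <- assign_producers(tis, pr, "binary", A, seed = 3)
  grd <- assign_producers(tis, pr, "graded", A, seed = 3)
  expect_equal(sum(bin$role == "producer"), 180)  # 0.75 * 0.6 * 400
  expect_equal(sum(grd$role == "producer"), 300)  # 0.75 * 400
  expect_true(all(bin$rate_scale[bin$role == "producer"] == 1))
  expect_equal(unique(grd$rate_scale[grd$role == "producer"]), 0.6)
  expect_equal(sum(bin$rate_scale), sum(grd$rate_scale), tolerance = 1e-9)
  # A = 0: no secretion in either mode
  expect_equal(sum(assign_producers(tis, pr, "binary", 0, seed = 1)$rate_scale), 0)
  expect_equal(sum(assign_producers(tis, pr, "graded", 0, seed = 1)$rate_scale), 0)
})

test_that("binary producers are a uniformly random subset", {
  pr <- default_profiles()
  par <- tiny_params(treg_frac = 0)
  tis <- place_cells(par, seed = 1)
  counts <- numeric(nrow(tis))
  n_draws <- 400
  for (s in seq_len(n_draws)) {
    b <- assign_producers(tis, pr, "binary", A = 0.15 / 0.65, seed = s)
    counts <- counts + (b$role == "producer")
  }
  n_prod <- sum(assign_producers(tis, pr, "binary", 0.15 / 0.65,
                                 seed = 1)$role == "producer")
  p_inc <- n_prod / nrow(tis)
  # each cell's inclusion frequency within 4 binomial sds of uniform
  tol <- 4 * sqrt(p_inc * (1 - p_inc) / n_draws)
  expect_true(all(abs(counts / n_draws - p_inc) < tol))
})

test_that("field is identically zero without producers and positive
          with them", {
  pr <- default_profiles()
  par <- tiny_params()
  tis <- assign_producers(place_cells(par, seed = 4), pr, "binary", 0, seed = 1)
  sol <- solve_field(tis, pr, t_end = 12)
  expect_true(all(sol$uptake$uptake == 0))
  expect_equal(sol$mass$secreted, 0)

  tis2 <- assign_producers(place_cells(par, seed = 4), pr, "binary", 1, seed = 1)
  sol2 <- solve_field(tis2, pr, snapshot_times = 9)
  expect_true(all(sol2$snapshots$t9 >= 0))
  expect_true(any(sol2$snapshots$t9 > 0))
  expect_gt(sum(sol2$uptake$uptake), 0)
})

test_that("single central producer reproduces the analytic log profile", {
  pr <- default_profiles()
  par <- model_params(n_cells = 1, domain_radius = 60, dx = 1.25, dt = 2,
                      D = 5e3, IL2R_max = c(Th = 0, Treg = 0), d_UR = 0,
                      IL2R_bg = 0, IL2_max = 3.6e4)
  tis <- manual_tissue(par, 0, 0)
  tis <- assign_producers(tis, pr, "binary", A = 1, seed = 1)
  sol <- solve_field(tis, pr, snapshot_times = 9)  # secretion factor = 1
  u <- sol$snapshots$t9; g <- sol$grid
  pref <- par$IL2_max / (2 * pi * par$D * par$slab) / 6.02214076e-4
  for (r in c(12, 20, 30, 40)) {
    pts <- rbind(c(r, 0), c(-r, 0), c(0, r), c(0, -r))
    grid_u <- mean(apply(pts, 1, function(p)
      u[which.min((g$x - p[1])^2 + (g$y - p[2])^2)]))
    expect_lt(abs(grid_u / (pref * log(60 / r)) - 1), 0.05)
  }
})

test_that("discrete mass ledger balances to well under 0.5% of secretion", {
  pr <- default_profiles()
  par <- tiny_params()
  tis <- assign_producers(place_cells(par, seed = 6), pr, "binary", 0.5,
                          seed = 7)
  sol <- solve_field(tis, pr)
  expect_gt(sol$mass$secreted, 0)
  expect_lt(abs(sol$mass$balance_error) / sol$mass$secreted, 0.005)
  expect_true(all(sol$u >= 0))
})

test_that("uptake saturates at the receptor capacity when IL-2 is in
          great excess", {
  pr <- default_profiles()
  par <- model_params(n_cells = 2, domain_radius = 60, dx = 2.5, dt = 0.5,
                      D = 5e3, IL2R_max = c(Th = 7e3, Treg = 2.2e4),
                      d_UR = 0, IL2R_bg = 0, IL2_max = 1e12)
  tis <- manual_tissue(par, c(0, 14), c(0, 0))
  tis <- assign_producers(tis, pr, "binary", A = 1, seed = 1)
  tis$role <- c("producer", "nonproducer")
  tis$rate_scale <- c(1, 0)
  sol <- solve_field(tis, pr)
  # saturated capture = capacity * integral of T_rec over the secretion
  # window [0, 18 h] = capacity * 9 h
  expect_equal(sol$uptake$uptake[2], 7e3 * 9, tolerance = 0.05 * 7e3 * 9)
})

test_that("activation fractions respond to the threshold as expected", {
  up <- data.frame(population = rep(c("Th", "Treg"), each = 5),
                   uptake = c(1:5, 11:15))
  expect_equal(activation_fractions(up, 0), c(Th = 1, Treg = 1))
  expect_equal(activation_fractions(up, Inf), c(Th = 0, Treg = 0))
  ths <- c(0, 2, 4, 8, 12, 20)
  fr <- vapply(ths, function(t) activation_fractions(up, t), c(Th = 0, Treg = 0))
  expect_true(all(diff(fr["Th", ]) <= 0))
  expect_true(all(diff(fr["Treg", ]) <= 0))
})

test_that("halving the grid spacing changes activated fractions by less
          than 2 percentage points", {
  pr <- default_profiles()
  par <- small_sweep_params()
  d <- vapply(3:5, function(s) {
    tis <- assign_producers(place_cells(par, seed = s), pr, "binary", 1,
                            seed = s + 100)
    f4 <- activation_fractions(solve_field(tis, pr)$uptake, 7.4e3)
    f2 <- activation_fractions(solve_field(tis, pr, dx = 2)$uptake, 7.4e3)
    f2 - f4
  }, c(Th = 0, Treg = 0))
  expect_lt(abs(mean(d["Th", ])), 0.02)
  expect_lt(abs(mean(d["Treg", ])), 0.02)
})

test_that("dose sweep fractions are zero at A = 0, monotone in stimulus,
          and Treg-dominated", {
  pr <- default_profiles()
  par <- small_sweep_params()
  sw <- run_dose_sweep("binary", c(0, 0.25, 1), 5, par, pr, seed = 2)
  fr <- sweep_fractions(sw, 7.4e3)
  for (p in c("Th", "Treg")) {
    v <- fr$fraction[fr$population == p]
    expect_equal(v[1], 0)
    expect_true(all(diff(v) > -0.03))  # non-decreasing up to noise
  }
  m <- matrix(fr$fraction, nrow = 2,
              dimnames = list(sort(unique(fr$population)), NULL))
  expect_true(all(m["Treg", ] >= m["Th", ]))
})

test_that("threshold calibration is self-consistent and handles the
          all-zero observation limit", {
  pr <- default_profiles()
  par <- small_sweep_params()
  sw <- run_dose_sweep("binary", c(0, 0.25, 1), 3, par, pr, seed = 3)
  theta <- 7.4e3
  fr <- sweep_fractions(sw, theta)
  cal <- calibrate_threshold(sw, fr[c("A", "population", "fraction")])
  expect_equal(sweep_fractions(sw, cal$threshold)$fraction, fr$fraction,
               tolerance = 1e-9)
  expect_lt(cal$sse, 1e-12)

  zeros <- fr[c("A", "population")]
  zeros$fraction <- 0
  cal0 <- calibrate_threshold(sw, zeros)
  expect_equal(cal0$threshold, 1e8)
  expect_lt(cal0$sse, 1e-12)
  expect_error(calibrate_threshold(sw, zeros[0, ]), "empty")
})

test_that("identical sweeps give identical scenario metrics", {
  pr <- default_profiles()
  par <- tiny_params()
  sw <- run_dose_sweep("binary", c(0, 0.5, 1), 2, par, pr, seed = 4)
  sw2 <- sw
  sw2$mode <- "graded"
  cmp <- compare_scenarios(sw, sw2, 5e3)
  df <- as.data.frame(cmp)
  b <- df[df$mode == "binary", c("h", "a50", "linear_width")]
  g <- df[df$mode == "graded", c("h", "a50", "linear_width")]
  rownames(b) <- rownames(g) <- NULL
  expect_equal(b, g)
})

test_that("solver rejects unresolved cells", {
  pr <- default_profiles()
  par <- tiny_params(dx = 6)  # coarser than the cell radius
  tis <- assign_producers(place_cells(tiny_params(), seed = 1), pr,
                          "binary", 1, seed = 1)
  expect_error(solve_field(tis, pr, dx = 6), "resolve")
})
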