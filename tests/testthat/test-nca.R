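test_that("profile construction validates monotone times and dose arithmetic", {
  p <- conc_profile(c(0, 1, 2), c(0, 5, 2), dose_mg_per_kg = 69,
                    body_weight_kg = 0.225)
  expect_equal(p$dose_mg, 69 * 0.225)
  expect_error(conc_profile(c(0, 1, 1), c(1, 2, 3)), "strictly increasing")
  expect_error(conc_profile(c(0, 1), c(1, 2)), "at least 3")
  expect_error(conc_profile(c(0, 1, 2), c(1, -2, 3)), ">= 0")
})

test_that("pseudo-subject assembly builds n profiles from a destructive table", {
  pk <- simulate_pk(residual_cv = 0.1, n_per_timepoint = 3, seed = 5)
  profs <- assemble_profiles(pk, "pseudo-subject")
  expect_length(profs, 3)
  expect_true(all(vapply(profs, function(p) length(p$times), integer(1)) == 17L))
  # i-th profile carries the i-th animal at each timepoint
  a2 <- pk[pk$animal == 2, ]
  expect_equal(profs[[2]]$conc, a2$conc_ng_ml[order(a2$time_h)])
  # unequal n refused
  expect_error(assemble_profiles(pk[-1, ], "pseudo-subject"), "same number")
})

test_that("mean-profile assembly averages animals per timepoint", {
  pk <- simulate_pk(residual_cv = 0.2, seed = 6)
  mp <- assemble_profiles(pk, "mean-profile")[[1]]
  t1 <- pk$time_h == pk$time_h[1]
  expect_equal(mp$conc[1], mean(pk$conc_ng_ml[t1]))
  expect_equal(attr(mp, "sd")[[1]], sd(pk$conc_ng_ml[t1]))
  # single animal per timepoint: both schemes coincide
  pk1 <- simulate_pk(residual_cv = 0.1, n_per_timepoint = 1, seed = 7)
  p_mean <- assemble_profiles(pk1, "mean-profile")[[1]]
  p_pseudo <- assemble_profiles(pk1, "pseudo-subject")[[1]]
  expect_equal(p_mean$conc, p_pseudo$conc)
})

test_that("cmax is the observed maximum and tmax the earliest time attaining it", {
  p <- conc_profile(c(0, 1, 2, 4), c(0, 10, 5, 1))
  s <- profile_summary(p)
  expect_equal(s$cmax, 10)
  expect_equal(s$tmax, 1)
  # tie: earliest time wins
  pt <- conc_profile(c(0, 1, 2, 4), c(0, 10, 10, 1))
  expect_equal(profile_summary(pt)$tmax, 1)
  expect_true(profile_summary(conc_profile(c(0, 1, 2), c(0, 0, 0)))$no_absorption)
  # on a noise-free oral curve the discrete tmax is the argmax over the grid
  grid <- pk_time_grid()
  cc <- bateman(grid, ka = 1.5, ke = 0.2, v_over_f = 0.3, dose_mg = 15)
  pb <- conc_profile(grid, cc)
  expect_equal(profile_summary(pb)$tmax, grid[which.max(cc)])
  # analytic tmax between the grid neighbours of the empirical argmax
  tstar <- log(1.5 / 0.2) / (1.5 - 0.2)
  i <- which.max(cc)
  expect_gte(tstar, grid[i - 1])
  expect_lte(tstar, grid[i + 1])
})

test_that("a mono-exponential tail gives lambda_z exactly", {
  tm <- c(0, 1, 2, 4, 8, 12, 24)
  p <- conc_profile(tm, 100 * exp(-0.2 * tm))
  lz <- fit_lambda_z(p)
  expect_equal(lz$lambda_z, 0.2, tolerance = 1e-10)
  expect_equal(lz$t_half, log(2) / 0.2, tolerance = 1e-10)
  expect_equal(lz$t_half * lz$lambda_z, log(2))
  # rising tails are refused
  up <- conc_profile(0:4, c(5, 1, 2, 3, 4))
  expect_error(fit_lambda_z(up), "nonpositive|not declining")
})

test_that("best-adjusted-R2 selection finds the terminal phase of a biphasic curve", {
  tm <- c(0.5, 1, 2, 3, 4, 6, 8, 12, 16, 20, 24)
  cc <- 400 * exp(-1.2 * tm) + 60 * exp(-0.15 * tm)
  set.seed(12)
  hits <- vapply(1:50, function(i) {
    p <- conc_profile(tm, cc * exp(rnorm(length(tm), 0, 0.02)))
    fit_lambda_z(p)$lambda_z
  }, numeric(1))
  # last 5 points are essentially mono-exponential at ke = 0.15
  expect_lt(abs(median(hits) - 0.15) / 0.15, 0.02)
})

test_that("manual tail selection honours the requested points", {
  tm <- c(0, 1, 2, 4, 8, 12, 24)
  p <- conc_profile(tm, 100 * exp(-0.25 * tm))
  lz <- fit_lambda_z(p, selection = "manual", indices = 5:7)
  expect_equal(lz$points, 5:7)
  expect_equal(lz$lambda_z, 0.25, tolerance = 1e-10)
  expect_error(fit_lambda_z(p, selection = "manual", indices = 6:7), ">= 3")
})

test_that("trapezoidal AUC and AUMC are exact on piecewise-linear profiles", {
  p <- conc_profile(c(0, 6, 24), c(100, 100, 100))
  a <- auc_aumc(p)
  expect_equal(a$auc_0_t, 2400)
  expect_equal(a$aumc_0_t, 24^2 / 2 * 100)   # integral of 100 t
  expect_equal(a$mrt, 12)
  # triangle 0 -> 100 over 0..10, then back to 0 at 24: AUC is exact on
  # linear segments; AUMC is the trapezoid applied to the moment curve
  p2 <- conc_profile(c(0, 10, 24), c(0, 100, 0))
  expect_equal(auc_aumc(p2)$auc_0_t, 0.5 * 100 * 24)
  expect_equal(auc_aumc(p2)$aumc_0_t,
               10 * (0 + 10 * 100) / 2 + 14 * (10 * 100 + 0) / 2)
  # AUC matches the quadrature of the interpolated curve
  expect_equal(auc_aumc(p2)$auc_0_t,
               integrate(function(t) approx(c(0, 10, 24), c(0, 100, 0),
                                            xout = t)$y, 0, 24)$value,
               tolerance = 1e-6)
  expect_error(auc_aumc(conc_profile(c(0, 2, 6), c(0, 5, 1))), "ends at")
})

test_that("AUC is additive over a partition of the window", {
  grid <- pk_time_grid()
  cc <- bateman(grid, 1.5, 0.2, 0.3, 15)
  p <- conc_profile(grid, cc)
  full <- auc_aumc(p, t_end = 24)$auc_0_t
  for (tstar in c(grid[5], grid[10], grid[15])) {
    left <- auc_aumc(p, t_end = tstar)$auc_0_t
    # right part: shift to a profile starting at tstar
    keep <- grid >= tstar
    pr <- conc_profile(grid[keep], cc[keep], dose_mg = NA)
    right <- auc_aumc(pr, t_end = 24, c0 = NULL)$auc_0_t
    expect_equal(left + right, full, tolerance = 1e-10)
  }
})

test_that("trapezoid on the sampling grid tracks the exact Bateman integral", {
  grid <- pk_time_grid()
  ka <- 1.5; ke <- 0.2; v <- 0.3; D <- 15
  p <- conc_profile(grid, bateman(grid, ka, ke, v, D))
  trap <- auc_aumc(p, t_end = 24)$auc_0_t
  exact <- bateman_integral(24, ka, ke, v, D)
  # discretization bound from the quadrature oracle: trapezoid error on a
  # grid refined 10x is an order of magnitude smaller, so the coarse-grid
  # deviation is the discretization error itself
  fine <- sort(unique(c(grid, seq(0, 24, by = 0.05))))
  pf_ <- conc_profile(fine, bateman(fine, ka, ke, v, D))
  trap_fine <- auc_aumc(pf_, t_end = 24)$auc_0_t
  bound <- abs(trap - trap_fine) + abs(trap_fine - exact) + 1e-9
  expect_lte(abs(trap - exact), bound)
  expect_lt(abs(trap - exact) / exact, 0.02)
})

test_that("mono-exponential profiles give lambda_z = ke and MRT near 1/ke", {
  tm <- seq(0, 60, by = 0.25)
  ke <- 0.25
  p <- conc_profile(tm, 100 * exp(-ke * tm))
  expect_equal(fit_lambda_z(p)$lambda_z, ke, tolerance = 1e-10)
  a <- auc_aumc(p, t_end = 60, c0 = NULL)
  # 60 h = 15 ln2/ke half-lives: truncation negligible, grid fine
  expect_lt(abs(a$mrt - 1 / ke) / (1 / ke), 0.01)
})

test_that("clearance and volume follow the dose/AUC and CL/lambda_z identities", {
  cv <- clearance_volume(auc_0_t = 300, lambda_z = 0.25, dose_mg = 15)
  expect_equal(cv$cl_f, 0.05)
  expect_equal(cv$v_f, 0.2)
  expect_equal(cv$v_f * 0.25, cv$cl_f)
  expect_error(clearance_volume(0, 0.2, 15), "positive")
  # parameter recovery on a dense, long grid (7+ half-lives)
  tm <- seq(0, 48, by = 0.1)
  ka <- 1.5; ke <- 0.2; v <- 0.3; D <- 15
  p <- conc_profile(tm, bateman(tm, ka, ke, v, D), dose_mg = D)
  a <- auc_aumc(p, t_end = 48)
  lz <- fit_lambda_z(p)
  cv2 <- clearance_volume(a$auc_0_t, lz$lambda_z, D)
  expect_lt(abs(cv2$cl_f - ke * v) / (ke * v), 0.05)
})

test_that("the NCA table reports the seven standard parameters per arm", {
  pk_s <- simulate_pk(residual_cv = 0.1, seed = 21, arm = "single")
  pk_m <- simulate_pk(residual_cv = 0.1, seed = 22, arm = "mixture",
                      v_over_f = 0.2)
  profs <- c(assemble_profiles(pk_s, dose_mg = 15.5),
             assemble_profiles(pk_m, dose_mg = 15.5))
  tab <- nca_table(profs)
  expect_setequal(unique(tab$parameter),
                  c("t_half", "tmax", "cmax", "auc_0_t", "v_f", "cl_f", "mrt"))
  expect_equal(nrow(tab), 14L)   # 7 parameters x 2 arms
  expect_true(all(tab$n == 3))
  # identical profiles collapse to sd 0; a single profile reports sd NA
  p <- assemble_profiles(simulate_pk(residual_cv = 0, seed = 1), dose_mg = 15.5)
  tab0 <- nca_table(p)
  expect_true(all(tab0$sd == 0))
  tab1 <- nca_table(p[1])
  expect_true(all(is.na(tab1$sd)))
  # hand check: t_half values 3 and 5 give mean 4, sd sqrt(2)
  expect_equal(sd(c(3, 5)), sqrt(2))
})

test_that("arm comparisons reproduce the pooled-t hand value and Welch symmetry", {
  cmp <- compare_arms(list(mean = 10, sd = 1, n = 3),
                      list(mean = 14, sd = 1, n = 3), var.equal = TRUE)
  expect_equal(cmp$t_statistic, -4.898979, tolerance = 1e-6)
  expect_equal(cmp$df, 4)
  set.seed(30)
  a <- rnorm(5, 10, 2); b <- rnorm(7, 12, 3)
  w1 <- compare_arms(a, b); w2 <- compare_arms(b, a)
  expect_equal(w1$p_value, w2$p_value)
  expect_equal(w1$t_statistic, -w2$t_statistic)
  # agreement with the reference implementation on raw data
  tt <- t.test(a, b)
  expect_equal(w1$t_statistic, unname(tt$statistic))
  expect_equal(w1$p_value, tt$p.value)
  same <- compare_arms(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("the null rejection rate of compare_arms is near the nominal 5%", {
  set.seed(99)
  rej <- 0L
  n_sim <- 2000
  for (i in seq_len(n_sim)) {
    a <- rnorm(10); b <- rnorm(10)
    rej <- rej + (compare_arms(a, b)$p_value < 0.05)
  }
  expect_gte(rej / n_sim, 0.03)
  expect_lte(rej / n_sim, 0.07)
})

test_that("the post-Tmax slope is the OLS slope on the linear scale", {
  tm <- c(0, 2, 4, 6, 8, 10, 12)
  p <- conc_profile(tm, c(0, 100, 80, 60, 40, 20, 0))
  expect_equal(post_tmax_slope(p), -10)
  flat <- conc_profile(c(0, 1, 2, 3), c(0, 50, 50, 50))
  expect_equal(post_tmax_slope(flat), 0)
  # independent OLS oracle on a sampled Bateman tail
  grid <- pk_time_grid()
  cc <- bateman(grid, 1.5, 0.2, 0.3, 15)
  pb <- conc_profile(grid, cc)
  i <- which.max(cc)
  x <- grid[i:length(grid)]; y <- cc[i:length(cc)]
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(post_tmax_slope(pb), beta, tolerance = 1e-10)
})
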