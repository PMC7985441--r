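test_that("transition matrices are proper and respect the state ordering", {
  pars <- default_parameters()
  for (arm in c("sorahaic", "sorafenib")) {
    for (k in c(0, 3, 20, 100)) {
      m <- build_transition_matrix(pars, arm, k)
      expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-12)
      expect_true(all(m >= 0 & m <= 1))
      expect_equal(unname(m["dead", ]), c(0, 0, 0, 1)) # absorbing
      expect_equal(unname(m[, "pfs"]), c(m["pfs", "pfs"], 0, 0, 0)) # no return to PFS
      expect_equal(m["rfs", "pfs"], 0)
    }
  }
})

test_that("RFS is absorbing when recurrence and background mortality vanish", {
  pars <- bare_params()
  m <- build_transition_matrix(pars, "sorahaic", 2)
  expect_equal(unname(m["rfs", ]), c(0, 1, 0, 0))
})

test_that("with OS equal to the PFS curve the excess progression probability is zero", {
  pars <- bare_params()
  pars$settings$pfs_death_rule <- "os_excess"
  pars$strategies$sorafenib$os_weibull <- pars$strategies$sorafenib$pfs_weibull
  for (k in 0:10)
    expect_equal(build_transition_matrix(pars, "sorafenib", k)["pfs", "pd"], 0)
})

test_that("the cycle-0 sorafenib matrix equals a hand-computed one", {
  pars <- default_parameters()
  # independent arithmetic from first principles (months convention);
  # OS scale recalibrated to the 7.13-month trial median by default
  u <- 21 / 30.4375
  s_pfs <- function(t) exp(-0.17 * t^1.295)
  os_scale <- log(2) / 7.13^1.48
  s_os <- function(t) exp(-os_scale * t^1.48)
  p_bg <- 1 - (1 - 0.00713)^(u / 12)
  p_exit <- 1 - s_pfs(u) / s_pfs(0)
  p_death <- max(1 - s_os(u) / s_os(0), p_bg)
  p_rec <- 1 - (1 - 0.335)^(u / 60)
  expected <- rbind(
    c(1 - min(p_exit, 1 - p_death) - p_death, 0, min(p_exit, 1 - p_death), p_death),
    c(0, 1 - p_rec - p_bg, p_rec, p_bg),
    c(0, 0, 1 - p_death, p_death),
    c(0, 0, 0, 1))
  m <- build_transition_matrix(pars, "sorafenib", 0)
  expect_equal(unname(m), unname(expected), tolerance = 1e-12)
})

test_that("the hepatectomy branch conserves occupancy and honours its cycle", {
  pars <- default_parameters()
  row <- c(pfs = 0.5, rfs = 0, pd = 0.3, dead = 0.2)
  out <- apply_hepatectomy_branch(row, pars, "sorahaic", 4)
  expect_equal(out[["rfs"]], 0.5 * 0.128)
  expect_equal(out[["pfs"]], 0.5 * (1 - 0.128))
  expect_equal(sum(out), 1)
  expect_equal(attr(out, "moved"), 0.064)
  # fraction 0 and 1 boundaries
  p0 <- pars; p0$strategies$sorahaic$hepatectomy_fraction <- 0
  expect_equal(as.numeric(apply_hepatectomy_branch(row, p0, "sorahaic", 4)),
               as.numeric(row))
  p1 <- pars; p1$strategies$sorahaic$hepatectomy_fraction <- 1
  expect_equal(apply_hepatectomy_branch(row, p1, "sorahaic", 4)[["pfs"]], 0)
  # called off-cycle: warning and no-op
  expect_warning(same <- apply_hepatectomy_branch(row, pars, "sorahaic", 7), "no-op")
  expect_equal(as.numeric(same), as.numeric(row))
})

test_that("cohort traces conserve occupancy and accumulate death monotonically", {
  pars <- default_parameters()
  for (arm in c("sorahaic", "sorafenib")) {
    tr <- run_cohort(pars, arm)
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, nrow(tr$occupancy)),
                 tolerance = 1e-10)
    expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-14))
  }
})

test_that("pre-branch cohort survival tracks the OS curve", {
  pars <- default_parameters()
  for (arm in c("sorahaic", "sorafenib")) {
    tr <- run_cohort(pars, arm)
    os <- strategy_curves(pars, arm)$os
    k <- 0:4
    alive <- 1 - tr$occupancy[k + 1, "dead"]
    expect_equal(unname(alive), survival_at(os, k * u_months), tolerance = 0.01)
  }
})

test_that("with full down-staging and no recurrence all survivors settle in RFS", {
  pars <- bare_params(max_cycles = 120L)
  pars$strategies$sorahaic$hepatectomy_fraction <- 1
  tr <- run_cohort(pars, "sorahaic")
  post <- tr$occupancy[(pars$settings$hepatectomy_branch_cycle + 1):nrow(tr$occupancy), ]
  expect_true(all(post[, "pfs"] == 0))
  # RFS occupancy is constant once entered (no recurrence, no background death)
  expect_equal(diff(range(post[, "rfs"])), 0, tolerance = 1e-12)
  expect_gt(post[1, "rfs"], 0.5)
})

test_that("the mortality-fraction horizon matches a brute-force inversion", {
  n <- 36
  pars <- bare_params(max_cycles = 200L)
  pars$settings$cycle_length_days <- 30.4375 # one-month cycles
  pars$settings$horizon_mode <- "mortality_fraction"
  lam <- log(100) / n
  for (arm in names(pars$strategies)) {
    pars$strategies[[arm]]$pfs_weibull <- list(scale = lam, shape = 1)
    pars$strategies[[arm]]$os_weibull <- list(scale = lam, shape = 1)
  }
  # independent oracle: smallest k with 1 - exp(-lam k) >= 0.99
  expected <- which(1 - exp(-lam * (1:200)) >= 0.99)[1]
  expect_equal(determine_horizon(pars), expected)
  expect_lte(abs(expected - n), 1) # ~n cycles by construction
  # threshold zero: nothing to run
  p0 <- pars; p0$settings$mortality_fraction_threshold <- 0
  expect_equal(determine_horizon(p0), 0L)
  # unreachable threshold errors with the residual alive fraction
  slow <- pars
  for (arm in names(slow$strategies))
    slow$strategies[[arm]]$os_weibull <- list(scale = 1e-4, shape = 1)
  slow$strategies$sorafenib$pfs_weibull <- list(scale = 1e-4, shape = 1)
  slow$strategies$sorahaic$pfs_weibull <- list(scale = 1e-4, shape = 1)
  expect_error(determine_horizon(slow), "alive", class = "haiccea_model_error")
})

test_that("microsimulation is seed-deterministic and unbiased for the cohort trace", {
  pars <- default_parameters()
  pars$settings$max_cycles <- 60L
  m1 <- microsimulate(pars, "sorahaic", 2000, seed = 7)
  m2 <- microsimulate(pars, "sorahaic", 2000, seed = 7)
  expect_identical(m1, m2)
  tr <- run_cohort(pars, "sorahaic")
  n <- 20000
  m <- microsimulate(pars, "sorahaic", n, seed = 11)
  p <- tr$occupancy
  tol <- 3 * sqrt(p * (1 - p) / n) + 3 / n
  expect_true(all(abs(m - p) <= tol))
})
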