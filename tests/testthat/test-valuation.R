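test_that("discount factors obey the closed forms", {
  expect_equal(discount_factor(c(0, 1, 7), 0), c(1, 1, 1))
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  # multiplicativity over split intervals
  expect_equal(discount_factor(0.6, 0.03) * discount_factor(1.1, 0.03) /
                 discount_factor(0, 0.03),
               discount_factor(1.7, 0.03), tolerance = 1e-12)
  expect_error(discount_factor(-1, 0.03), class = "haiccea_model_error")
  expect_error(discount_factor(1, -1.5), class = "haiccea_model_error")
})

test_that("state cycle costs follow the accrual rules", {
  pars <- default_parameters()
  pc <- pars$costs$per_cycle
  expect_equal(state_cycle_cost("dead", pars, "sorahaic", 3), 0)
  # monotherapy PFS beyond cycle 0: drug + tests + persisting HFS management
  expect_equal(state_cycle_cost("pfs", pars, "sorafenib", 1),
               2308.32 + 352.19 + 0.14 * 11.54)
  # combination PFS at cycle 0: hand-summed from all listed components
  chemo <- (273.31 + 514.65 + 23.74) * pars$costs$bsa_patient / 1.72
  sae_lump <- 0.40 * 42.54 + 0.097 * 82.39 + 0.089 * 5.66 + 0.14 * 48.35
  expect_equal(state_cycle_cost("pfs", pars, "sorahaic", 0),
               2308.32 + chemo + 1817.03 + 376.92 + 352.19 +
                 0.10 * 11.54 + sae_lump,
               tolerance = 1e-9)
  # RFS is surveillance only (plus persisting HFS under the default scope)
  expect_equal(state_cycle_cost("rfs", pars, "sorahaic", 9),
               352.19 + 0.10 * 11.54)
  # PD under the default BSC rule, and under the subsequent-treatment mix
  expect_equal(state_cycle_cost("pd", pars, "sorahaic", 9), 357 + 0.10 * 11.54)
  mixed <- pars
  mixed$settings$pd_cost_mode <- "mix"
  haic_reg <- chemo + 1817.03 + 376.92
  expect_equal(state_cycle_cost("pd", mixed, "sorahaic", 9),
               0.30 * 2308.32 + 0.29 * haic_reg + 0.41 * 357 + 0.10 * 11.54,
               tolerance = 1e-9)
  expect_error(state_cycle_cost("limbo", pars, "sorahaic", 0),
               class = "haiccea_model_error")
})

test_that("BSA scales only the body-surface-dosed chemotherapy drugs", {
  pars <- default_parameters()
  base <- state_cycle_cost("pfs", pars, "sorahaic", 1)
  pars$costs$bsa_patient <- 2 * 1.72
  up <- state_cycle_cost("pfs", pars, "sorahaic", 1)
  expect_equal(up - base, 273.31 + 514.65 + 23.74, tolerance = 1e-9)
  # the monotherapy arm has no BSA-dosed component
  expect_equal(state_cycle_cost("pfs", pars, "sorafenib", 1),
               state_cycle_cost("pfs", default_parameters(), "sorafenib", 1))
})

test_that("state cycle QALYs reduce to utility times time without adverse events", {
  pars <- default_parameters()
  expect_equal(state_cycle_qaly("dead", pars, "sorahaic", 2, u_years), 0)
  clean <- pars
  for (s in names(clean$utilities$disutility)) clean$utilities$disutility[[s]] <- 0
  clean$ranges$disutility_neutropenia <- list(min = 0, max = 0, dist = "beta")
  clean$ranges$disutility_hfs <- list(min = 0, max = 0, dist = "beta")
  clean$ranges$disutility_diarrhea <- list(min = 0, max = 0, dist = "beta")
  clean$ranges$disutility_nausea_vomiting <- list(min = 0, max = 0, dist = "beta")
  expect_equal(state_cycle_qaly("pd", clean, "sorafenib", 5, 1), 0.68)
  expect_equal(state_cycle_qaly("pfs", clean, "sorahaic", 3, u_years),
               0.76 * u_years)
  # HFS disutility persists each cycle; transient decrements hit cycle 0 only
  expect_equal(state_cycle_qaly("pfs", pars, "sorahaic", 3, u_years),
               (0.76 - 0.10 * 0.016) * u_years)
  lump <- 0.097 * 0.09 + 0.089 * 0.047 + 0.14 * 0.048 # ALT/AST disutility is 0
  expect_equal(state_cycle_qaly("pfs", pars, "sorahaic", 0, u_years),
               (0.76 - 0.10 * 0.016 - lump) * u_years, tolerance = 1e-12)
})

test_that("accrual over a hand-built toy trace matches arithmetic", {
  pars <- default_parameters()
  occ <- rbind(c(1, 0, 0, 0),
               c(0.6, 0, 0.3, 0.1),
               c(0.4, 0, 0.3, 0.3))
  colnames(occ) <- c("pfs", "rfs", "pd", "dead")
  trace <- structure(
    list(occupancy = occ, time_months = (0:2) * u_months,
         strategy_id = "sorafenib", branch = list(cycle = 4, moved = 0),
         n_cycles = 2L),
    class = "cohort_trace")
  got <- accrue(trace, pars)
  d <- discount_factor((0:1) * u_months / 12, 0.03)
  c0 <- state_cycle_cost("pfs", pars, "sorafenib", 0)
  c1 <- state_cycle_cost("pfs", pars, "sorafenib", 1)
  cpd <- state_cycle_cost("pd", pars, "sorafenib", 1)
  expect_equal(got$total_cost,
               d[1] * (1 * c0) + d[2] * (0.6 * c1 + 0.3 * cpd), tolerance = 1e-9)
  q0 <- state_cycle_qaly("pfs", pars, "sorafenib", 0, u_years)
  q1 <- state_cycle_qaly("pfs", pars, "sorafenib", 1, u_years)
  qpd <- state_cycle_qaly("pd", pars, "sorafenib", 1, u_years)
  expect_equal(got$total_qalys,
               d[1] * q0 + d[2] * (0.6 * q1 + 0.3 * qpd), tolerance = 1e-12)
  expect_equal(got$total_lys, (d[1] * 1 + d[2] * 0.9) * u_years, tolerance = 1e-12)
  expect_equal(sum(got$breakdown), got$total_cost, tolerance = 1e-6)
})

test_that("accrual satisfies its global inequalities and linearity", {
  pars <- default_parameters()
  tr <- run_cohort(pars, "sorahaic")
  acc <- accrue(tr, pars)
  expect_equal(sum(acc$breakdown), acc$total_cost, tolerance = 1e-6)
  expect_lte(acc$total_qalys, acc$total_lys) # utilities <= 1
  # discounted <= undiscounted at positive rates
  und <- pars
  und$settings$discount_rate_annual <- 0
  acc0 <- accrue(run_cohort(und, "sorahaic"), und)
  expect_lt(acc$total_cost, acc0$total_cost)
  expect_lt(acc$total_qalys, acc0$total_qalys)
  # doubling every cost input exactly doubles total cost
  dbl <- pars
  dbl$costs$per_cycle <- lapply(dbl$costs$per_cycle, `*`, 2)
  dbl$costs$one_time <- lapply(dbl$costs$one_time, `*`, 2)
  dbl$ranges <- lapply(stats::setNames(nm = names(dbl$ranges)), function(nm) {
    r <- dbl$ranges[[nm]]
    if (startsWith(nm, "cost_")) { r$min <- r$min * 2; r$max <- r$max * 2 }
    r
  })
  acc2 <- accrue(run_cohort(dbl, "sorahaic"), dbl)
  expect_equal(acc2$total_cost, 2 * acc$total_cost, tolerance = 1e-9)
  # zero-cost bundle accrues nothing
  zero <- pars
  zero$costs$per_cycle <- lapply(zero$costs$per_cycle, function(x) 0)
  zero$costs$one_time <- lapply(zero$costs$one_time, function(x) 0)
  zero$ranges <- lapply(stats::setNames(nm = names(zero$ranges)), function(nm) {
    r <- zero$ranges[[nm]]
    if (startsWith(nm, "cost_")) { r$min <- 0; r$max <- 0 }
    r
  })
  expect_equal(accrue(run_cohort(zero, "sorahaic"), zero)$total_cost, 0)
})

test_that("half-cycle correction values cycles at mid-occupancy", {
  pars <- default_parameters()
  hcc <- pars
  hcc$settings$half_cycle_correction <- TRUE
  a <- accrue(run_cohort(pars, "sorafenib"), pars)
  b <- accrue(run_cohort(hcc, "sorafenib"), hcc)
  # occupancy declines, so averaging start/end lowers every total
  expect_lt(b$total_lys, a$total_lys)
  expect_lt(b$total_cost, a$total_cost)
})
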