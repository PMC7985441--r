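test_that("setting one mix component renormalises its complement", {
  pars <- default_parameters()
  out <- set_parameter_value(pars, "mix_sorahaic_sorafenib", 0.5)
  mix <- unlist(out$strategies$sorahaic$subsequent_mix)
  expect_equal(sum(mix), 1, tolerance = 1e-12)
  expect_equal(unname(mix["sorafenib"]), 0.5)
  # the other two keep their relative weights (0.29 : 0.41)
  expect_equal(mix[["haic"]] / mix[["bsc"]], 0.29 / 0.41, tolerance = 1e-12)
  expect_error(set_parameter_value(pars, "no_such_param", 1),
               class = "haiccea_validation_error")
})

test_that("a degenerate one-way sweep has zero span and cost sweeps are monotone", {
  pars <- default_parameters()
  sw <- one_way_sweep(pars, "utility_pd", low = 0.68, high = 0.68)
  expect_equal(sw$span, 0)
  # raising the HAIC per-cycle cost raises the ICER monotonically
  sw2 <- one_way_sweep(pars, "cost_haic_procedure")
  expect_lt(sw2$icer_at_low, sw2$icer_at_high)
  mid <- one_way_sweep(pars, "cost_haic_procedure",
                       low = sw2$low, high = (sw2$low + sw2$high) / 2)
  expect_lt(mid$icer_at_high, sw2$icer_at_high)
})

test_that("the tornado covers every ranged parameter, sorted by span", {
  pars <- default_parameters()
  tor <- tornado(pars)
  expect_setequal(tor$param_id, psa_specs(pars)$param_id)
  s <- tor$span[!is.na(tor$span)]
  expect_true(all(diff(s) <= 1e-12))
  # collapsing every range onto its base flattens all spans to zero
  flat <- pars
  specs <- psa_specs(pars)
  for (i in seq_len(nrow(specs))) {
    id <- specs$param_id[i]
    flat$ranges[[id]] <- list(min = specs$base[i], max = specs$base[i],
                              dist = "fixed")
  }
  tflat <- tornado(flat)
  expect_true(all(tflat$span == 0))
})

test_that("PSA sampling is deterministic, respects fixed parameters and its moments", {
  pars <- default_parameters()
  s1 <- sample_parameters(pars, 123)
  s2 <- sample_parameters(pars, 123)
  expect_identical(attr(s1, "sampled"), attr(s2, "sampled"))
  # discount rate is declared fixed and never moves
  expect_equal(s1$settings$discount_rate_annual, 0.03)
  # the sampled mix still sums to one
  expect_equal(sum(unlist(s1$strategies$sorahaic$subsequent_mix)), 1,
               tolerance = 1e-12)
  # law of large numbers: mean of utility_pd draws ~ base, sd ~ (max-min)/3.92
  draws <- vapply(1:2000, function(i)
    attr(sample_parameters(pars, 5000 + i), "sampled")[["utility_pd"]], 0)
  expect_equal(mean(draws), 0.68, tolerance = 0.005)
  expect_equal(sd(draws), (0.82 - 0.54) / 3.92, tolerance = 0.05)
  # every draw lies in its distribution's support
  expect_true(all(draws > 0 & draws < 1))
})

test_that("PSA collapses to the base case when every distribution is fixed", {
  pars <- default_parameters()
  specs <- psa_specs(pars)
  for (i in seq_len(nrow(specs)))
    pars$ranges[[specs$param_id[i]]] <-
      list(min = specs$base[i], max = specs$base[i], dist = "fixed")
  psa <- run_psa(pars, n_draws = 1, seed = 9)
  base <- base_case(pars)
  expect_equal(psa$delta_cost, base$delta_cost, tolerance = 1e-9)
  expect_equal(psa$delta_qalys, base$delta_qalys, tolerance = 1e-9)
})

test_that("PSA draws are reproducible and form stable substreams", {
  pars <- default_parameters()
  pars$settings$max_cycles <- 60L # keep the loop cheap
  a <- run_psa(pars, n_draws = 6, seed = 31)
  b <- run_psa(pars, n_draws = 6, seed = 31)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # adding draws never changes earlier draws
  c8 <- run_psa(pars, n_draws = 8, seed = 31)
  expect_equal(as.data.frame(c8)[1:6, ], as.data.frame(a), tolerance = 1e-12)
  # a different seed gives different samples with the same schema
  d <- run_psa(pars, n_draws = 6, seed = 32)
  expect_identical(names(d), names(a))
  expect_false(identical(d$delta_cost, a$delta_cost))
})

test_that("the acceptability curve equals its defining identities", {
  samples <- data.frame(delta_cost = c(-10, -5, 20, 40),
                        delta_qalys = c(1, 2, 1, 0.5))
  cc <- ceac(samples, c(0, 10, 40, 100))
  # at zero WTP, acceptability is the fraction of cost-saving draws
  expect_equal(cc$acceptability[1], mean(samples$delta_cost < 0))
  # all draws dominant: acceptability 1 everywhere
  dom <- data.frame(delta_cost = c(-1, -2), delta_qalys = c(0.5, 1))
  expect_true(all(ceac(dom, c(0, 1e5))$acceptability == 1))
  # monotone non-decreasing in WTP when every draw gains QALYs
  expect_true(all(diff(cc$acceptability) >= 0))
  expect_error(ceac(samples[0, ], 0), class = "haiccea_model_error")
})
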