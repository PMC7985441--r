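# shared fixtures built in code

# bundle with every stochastic/structural frill switched off: exponential-ish
# handling stays, but zero recurrence, zero background mortality and no
# hepatectomy make closed-form reasoning easy
bare_params <- function(max_cycles = 60L) {
  pars <- default_parameters()
  pars$settings$os_median_calibration <- "none"
  pars$settings$max_cycles <- as.integer(max_cycles)
  pars$mortality$flat_annual_probability <- 0
  pars$recurrence$cumulative_incidence <- 0
  for (arm in names(pars$strategies))
    pars$strategies[[arm]]$hepatectomy_fraction <- 0
  # widen the affected ranges so the stripped-down bases stay bracketed
  pars$ranges$hepatectomy_sorahaic <- list(min = 0, max = 1, dist = "beta")
  pars$ranges$hepatectomy_sorafenib <- list(min = 0, max = 1, dist = "beta")
  pars$ranges$recurrence_rate <- list(min = 0, max = 0.9, dist = "beta")
  pars
}

# cycle length in months under the default 21-day cycle
u_months <- 21 / 30.4375
u_years <- 21 / 365.25

# independent Weibull survival oracle via the base-R parameterisation:
# stats::pweibull uses S(t) = exp(-(t/b)^a), so b = lambda^(-1/gamma)
pweibull_surv <- function(scale, shape, t)
  stats::pweibull(t, shape = shape, scale = scale^(-1 / shape), lower.tail = FALSE)
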