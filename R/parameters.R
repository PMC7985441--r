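#' Default model parameters
#'
#' Returns the complete parameter bundle of the cost-effectiveness model:
#' Weibull survival curves per strategy and endpoint, per-cycle and one-time
#' costs in 2019 US dollars, health-state utilities and adverse-event
#' disutilities, treatment proportions, recurrence risk after down-staging
#' hepatectomy, background mortality, model settings, and the ranges /
#' distribution families used by the deterministic and probabilistic
#' sensitivity analyses.
#'
#' Two corrections relative to the published parameter table are applied by
#' default and are both reversible:
#' \itemize{
#'   \item `os_shape = "corrected"` reads the combination arm's
#'     overall-survival shape as 1.39235. The printed value 0.139235 implies
#'     a median OS of roughly \eqn{10^{10}} months and leaves most of the
#'     cohort alive after decades, which contradicts the trial's median OS of
#'     13.37 months and the model's own published 8-year horizon; it is
#'     treated as a decimal-point typo. Use `os_shape = "printed"` for the
#'     value verbatim.
#'   \item `settings$os_median_calibration = "scale"` rescales both arms'
#'     OS curves so their medians equal the trial medians (13.37 and 7.13
#'     months); the printed fits undershoot both by a common factor of about
#'     1.36 while matching the PFS medians, suggesting an axis-scale issue in
#'     the digitization. Set to `"none"` to use the table values as printed,
#'     or `"shape"` to refit the shape holding the scale.
#' }
#'
#' @param os_shape `"corrected"` (default) or `"printed"`; see Details.
#' @return A validated parameter bundle of class `haic_params`.
#' @examples
#' pars <- default_parameters()
#' pars$costs$per_cycle$sorafenib
#' pars$strategies$sorahaic$pfs_weibull
#' @export
default_parameters <- function(os_shape = c("corrected", "printed")) {
  os_shape <- match.arg(os_shape)
  pars <- default_parameters_raw(os_shape)
  validate_parameters(pars)
  pars
}

default_parameters_raw <- function(os_shape = "corrected") {
  pars <- list(
    settings = list(
      cycle_length_days = 21,
      discount_rate_annual = 0.03,
      horizon_mode = "fixed_cycles",
      mortality_fraction_threshold = 0.99,
      max_cycles = 139L,
      half_cycle_correction = FALSE,
      pd_cost_mode = "bsc",
      pfs_death_rule = "os_competing",
      os_median_calibration = "scale",
      hfs_scope = "alive",
      hepatectomy_branch_cycle = 4L,
      wtp_thresholds = list(China = 30492, Beijing = 72000,
                            Fujian = 47285, Gansu = 14595),
      currency_rate_cny_per_usd = 6.77,
      costs_currency = "USD",
      random_seed = 20190101L
    ),
    costs = list(
      per_cycle = list(
        sorafenib = 2308.32,
        oxaliplatin = 273.31,
        fluorouracil = 514.65,
        leucovorin = 23.74,
        haic_procedure = 1817.03,
        hospitalization = 376.92,
        test = 352.19,
        bsc = 357,
        hfs = 11.54
      ),
      one_time = list(
        hepatectomy = 8862.63,
        elevated_alt_ast = 42.54,
        neutropenia = 82.39,
        diarrhea = 5.66,
        nausea_vomiting = 48.35
      ),
      bsa_reference = 1.72,
      bsa_patient = 1.72
    ),
    utilities = list(
      pfs = 0.76,
      pd = 0.68,
      disutility = list(
        elevated_alt_ast = 0,
        neutropenia = 0.09,
        hfs = 0.016,
        diarrhea = 0.047,
        nausea_vomiting = 0.048
      )
    ),
    recurrence = list(
      crs_score = 1L,
      cumulative_incidence = 0.335,
      horizon_years = 5
    ),
    mortality = list(flat_annual_probability = 0.00713),
    strategies = list(
      sorahaic = list(
        name = "SoraHAIC",
        uses_haic = TRUE,
        pfs_weibull = list(scale = 0.0985, shape = 0.97),
        os_weibull = list(scale = 0.02858,
                          shape = if (os_shape == "corrected") 1.39235 else 0.139235),
        os_target_median_months = 13.37,
        hepatectomy_fraction = 0.128,
        sae_incidence = list(elevated_alt_ast = 0.40, neutropenia = 0.097,
                             hfs = 0.10, diarrhea = 0.089, nausea_vomiting = 0.14),
        subsequent_mix = list(sorafenib = 0.30, haic = 0.29, bsc = 0.41)
      ),
      sorafenib = list(
        name = "Sorafenib",
        uses_haic = FALSE,
        pfs_weibull = list(scale = 0.17, shape = 1.295),
        os_weibull = list(scale = 0.06, shape = 1.48),
        os_target_median_months = 7.13,
        hepatectomy_fraction = 0.0082,
        sae_incidence = list(elevated_alt_ast = 0.34, neutropenia = 0.025,
                             hfs = 0.14, diarrhea = 0.12, nausea_vomiting = 0.025),
        # published proportions 0.35/0.33/0.33 sum to 1.01 (rounding);
        # renormalised so the mix invariant holds
        subsequent_mix = list(sorafenib = 0.35 / 1.01, haic = 0.33 / 1.01,
                              bsc = 0.33 / 1.01)
      )
    ),
    ranges = list(
      utility_pfs = list(min = 0.61, max = 0.91, dist = "beta"),
      utility_pd = list(min = 0.54, max = 0.82, dist = "beta"),
      cost_sorafenib = list(min = 1846.66, max = 2769.98, dist = "gamma"),
      cost_oxaliplatin = list(min = 218.65, max = 327.97, dist = "gamma"),
      cost_fluorouracil = list(min = 411.72, max = 617.58, dist = "gamma"),
      cost_leucovorin = list(min = 18.99, max = 28.49, dist = "gamma"),
      cost_haic_procedure = list(min = 1453.62, max = 2180.44, dist = "gamma"),
      cost_hepatectomy = list(min = 7090.10, max = 10635.16, dist = "gamma"),
      cost_hospitalization = list(min = 301.54, max = 452.3, dist = "gamma"),
      cost_test = list(min = 281.75, max = 422.63, dist = "gamma"),
      cost_bsc = list(min = 167.64, max = 847.84, dist = "gamma"),
      cost_sae_elevated_alt_ast = list(min = 33.04, max = 49.56, dist = "gamma"),
      cost_sae_neutropenia = list(min = 65.91, max = 98.87, dist = "gamma"),
      cost_sae_hfs = list(min = 9.23, max = 11.54, dist = "gamma"),
      cost_sae_diarrhea = list(min = 4.53, max = 6.79, dist = "gamma"),
      cost_sae_nausea_vomiting = list(min = 38.68, max = 58.02, dist = "gamma"),
      disutility_neutropenia = list(min = 0.059, max = 0.12, dist = "beta"),
      disutility_hfs = list(min = 0.013, max = 0.019, dist = "beta"),
      disutility_diarrhea = list(min = 0.016, max = 0.077, dist = "beta"),
      disutility_nausea_vomiting = list(min = 0.038, max = 0.058, dist = "beta"),
      inc_sorahaic_elevated_alt_ast = list(min = 0.32, max = 0.48, dist = "beta"),
      inc_sorahaic_neutropenia = list(min = 0.077, max = 0.12, dist = "beta"),
      inc_sorahaic_hfs = list(min = 0.084, max = 0.13, dist = "beta"),
      inc_sorahaic_diarrhea = list(min = 0.071, max = 0.11, dist = "beta"),
      inc_sorahaic_nausea_vomiting = list(min = 0.11, max = 0.16, dist = "beta"),
      inc_sorafenib_elevated_alt_ast = list(min = 0.27, max = 0.41, dist = "beta"),
      inc_sorafenib_neutropenia = list(min = 0.02, max = 0.03, dist = "beta"),
      inc_sorafenib_hfs = list(min = 0.11, max = 0.17, dist = "beta"),
      inc_sorafenib_diarrhea = list(min = 0.099, max = 0.15, dist = "beta"),
      inc_sorafenib_nausea_vomiting = list(min = 0.02, max = 0.03, dist = "beta"),
      hepatectomy_sorahaic = list(min = 0.10, max = 0.15, dist = "beta"),
      hepatectomy_sorafenib = list(min = 0.0066, max = 0.0098, dist = "beta"),
      mix_sorahaic_sorafenib = list(min = 0.24, max = 0.36, dist = "beta"),
      mix_sorahaic_haic = list(min = 0.23, max = 0.35, dist = "beta"),
      mix_sorahaic_bsc = list(min = 0.33, max = 0.49, dist = "beta"),
      mix_sorafenib_sorafenib = list(min = 0.28, max = 0.42, dist = "beta"),
      mix_sorafenib_haic = list(min = 0.26, max = 0.39, dist = "beta"),
      mix_sorafenib_bsc = list(min = 0.26, max = 0.39, dist = "beta"),
      bsa = list(min = 1.38, max = 2.06, dist = "normal"),
      recurrence_rate = list(min = 0.313, max = 0.341, dist = "beta"),
      discount_rate = list(min = 0, max = 0.05, dist = "fixed")
    )
  )
  class(pars) <- "haic_params"
  pars
}

#' @export
print.haic_params <- function(x, ...) {
  s <- x$settings
  cat("Markov cohort CEA parameter bundle\n")
  cat(sprintf("  strategies: %s\n",
              paste(vapply(x$strategies, `[[`, "", "name"), collapse = " vs ")))
  cat(sprintf("  cycle %g days, discount %g%%/yr, horizon %s (max %d cycles)\n",
              s$cycle_length_days, 100 * s$discount_rate_annual,
              s$horizon_mode, s$max_cycles))
  cat(sprintf("  death rule '%s', PD costing '%s', OS calibration '%s'\n",
              s$pfs_death_rule, s$pd_cost_mode, s$os_median_calibration))
  invisible(x)
}

# ---- validation -----------------------------------------------------------

SAE_TYPES <- c("elevated_alt_ast", "neutropenia", "hfs", "diarrhea", "nausea_vomiting")

# recursively reject keys absent from the reference skeleton
check_unknown_keys <- function(x, ref, where = "") {
  if (!is.list(x) || !is.list(ref)) return(invisible(TRUE))
  if (is.null(names(ref))) return(invisible(TRUE))
  extra <- setdiff(names(x), names(ref))
  if (length(extra))
    abort_validation(sprintf("unknown key(s): %s",
                             paste0(where, extra, collapse = ", ")))
  for (nm in intersect(names(x), names(ref)))
    check_unknown_keys(x[[nm]], ref[[nm]], paste0(where, nm, "$"))
  invisible(TRUE)
}

validate_strategy <- function(st, id) {
  for (f in c("name", "uses_haic", "pfs_weibull", "os_weibull",
              "hepatectomy_fraction", "sae_incidence", "subsequent_mix"))
    if (is.null(st[[f]]))
      abort_validation("missing strategy field", paste(id, f, sep = "$"))
  as_weibull_params(st$pfs_weibull)
  as_weibull_params(st$os_weibull)
  check_probability(st$hepatectomy_fraction, paste0(id, "$hepatectomy_fraction"))
  for (s in SAE_TYPES)
    check_probability(st$sae_incidence[[s]], paste0(id, "$sae_incidence$", s))
  mix <- unlist(st$subsequent_mix[c("sorafenib", "haic", "bsc")])
  if (length(mix) != 3L || any(is.na(mix)))
    abort_validation("subsequent_mix needs sorafenib, haic, bsc entries", id)
  for (m in mix) check_probability(m, paste0(id, "$subsequent_mix"))
  if (abs(sum(mix) - 1) > 1e-9)
    abort_validation(sprintf("subsequent_mix sums to %.6f, not 1", sum(mix)),
                     paste0(id, "$subsequent_mix"))
  invisible(TRUE)
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant of the bundle: positivity of Weibull
#' parameters and costs, probabilities and utilities in \[0, 1\], the
#' subsequent-treatment mix summing to 1, range bounds bracketing base
#' values, known settings enums, and absence of unknown keys. All bundles,
#' including [default_parameters()] and anything read by
#' [load_parameters()], pass through this single validator.
#'
#' @param pars a parameter bundle.
#' @return Invisibly `TRUE`; otherwise a classed
#'   `haiccea_validation_error` naming the offending field.
#' @export
validate_parameters <- function(pars) {
  check_unknown_keys(unclass(pars), params_skeleton())

  s <- pars$settings
  if (is.null(s)) abort_validation("missing settings block")
  check_number(s$cycle_length_days, "settings$cycle_length_days",
               min = .Machine$double.xmin)
  check_number(s$discount_rate_annual, "settings$discount_rate_annual", 0, 1)
  if (!s$horizon_mode %in% c("fixed_cycles", "mortality_fraction"))
    abort_validation("horizon_mode must be fixed_cycles or mortality_fraction")
  check_number(s$mortality_fraction_threshold,
               "settings$mortality_fraction_threshold", 0, 1)
  check_number(s$max_cycles, "settings$max_cycles", min = 1)
  if (!is.logical(s$half_cycle_correction))
    abort_validation("half_cycle_correction must be logical")
  if (!s$pd_cost_mode %in% c("bsc", "mix"))
    abort_validation("pd_cost_mode must be 'bsc' or 'mix'")
  if (!s$pfs_death_rule %in% c("os_competing", "os_excess", "background"))
    abort_validation("pfs_death_rule must be os_competing, os_excess or background")
  if (!s$os_median_calibration %in% c("scale", "shape", "none"))
    abort_validation("os_median_calibration must be scale, shape or none")
  if (!s$hfs_scope %in% c("alive", "on_treatment"))
    abort_validation("hfs_scope must be 'alive' or 'on_treatment'")
  check_number(s$hepatectomy_branch_cycle, "settings$hepatectomy_branch_cycle", min = 0)
  if (length(s$wtp_thresholds) == 0L)
    abort_validation("at least one WTP threshold required")
  for (w in names(s$wtp_thresholds))
    check_number(s$wtp_thresholds[[w]], paste0("wtp_thresholds$", w),
                 min = .Machine$double.xmin)
  check_number(s$currency_rate_cny_per_usd, "settings$currency_rate_cny_per_usd",
               min = .Machine$double.xmin)
  if (!s$costs_currency %in% c("USD", "CNY"))
    abort_validation("costs_currency must be USD or CNY")

  for (nm in names(pars$costs$per_cycle))
    check_number(pars$costs$per_cycle[[nm]], paste0("costs$per_cycle$", nm), min = 0)
  for (nm in names(pars$costs$one_time))
    check_number(pars$costs$one_time[[nm]], paste0("costs$one_time$", nm), min = 0)
  check_number(pars$costs$bsa_reference, "costs$bsa_reference",
               min = .Machine$double.xmin)
  check_number(pars$costs$bsa_patient, "costs$bsa_patient",
               min = .Machine$double.xmin)

  check_probability(pars$utilities$pfs, "utilities$pfs")
  check_probability(pars$utilities$pd, "utilities$pd")
  for (sae in SAE_TYPES)
    check_number(pars$utilities$disutility[[sae]],
                 paste0("utilities$disutility$", sae), 0, 1)

  check_number(pars$recurrence$cumulative_incidence,
               "recurrence$cumulative_incidence", 0, 1 - 1e-12)
  check_number(pars$recurrence$horizon_years, "recurrence$horizon_years",
               min = .Machine$double.xmin)
  check_probability(pars$mortality$flat_annual_probability,
                    "mortality$flat_annual_probability")

  if (!setequal(names(pars$strategies), c("sorahaic", "sorafenib")))
    abort_validation("strategies must contain exactly 'sorahaic' and 'sorafenib'")
  for (id in names(pars$strategies))
    validate_strategy(pars$strategies[[id]], id)

  reg <- param_registry()
  for (nm in names(pars$ranges)) {
    r <- pars$ranges[[nm]]
    if (!nm %in% reg$param_id)
      abort_validation("range for unknown parameter id", nm)
    check_number(r$min, paste0("ranges$", nm, "$min"))
    check_number(r$max, paste0("ranges$", nm, "$max"))
    if (r$min > r$max) abort_validation("min > max", paste0("ranges$", nm))
    if (!r$dist %in% c("beta", "gamma", "normal", "fixed"))
      abort_validation("dist must be beta, gamma, normal or fixed",
                       paste0("ranges$", nm))
    base <- pluck_path(pars, reg$path[[match(nm, reg$param_id)]])
    if (base < r$min - 1e-9 || base > r$max + 1e-9)
      abort_validation(sprintf("base value %g outside range [%g, %g]",
                               base, r$min, r$max), paste0("ranges$", nm))
    if (r$dist == "beta" && (r$min < 0 || r$max > 1 || base < 0 || base > 1))
      abort_validation("beta distribution requires support within [0, 1]",
                       paste0("ranges$", nm))
  }
  invisible(TRUE)
}

# name skeleton used for unknown-key rejection (values irrelevant)
params_skeleton <- function() {
  if (is.null(.haiccea_cache$skeleton))
    .haiccea_cache$skeleton <- unclass(default_parameters_raw())
  .haiccea_cache$skeleton
}

.haiccea_cache <- new.env(parent = emptyenv())

# ---- config I/O -----------------------------------------------------------

#' Read a parameter bundle from a YAML or JSON configuration file
#'
#' The file must follow the schema of the bundled baseline configuration
#' (`system.file("extdata", "paper_baseline.yaml", package = "haiccea")`),
#' which carries the published parameter set. Every field is validated and
#' unknown keys are rejected. If `settings$costs_currency` is `"CNY"`, all
#' cost entries and cost ranges are converted to USD on load using
#' `settings$currency_rate_cny_per_usd`; USD configurations pass through
#' untouched.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `haic_params` bundle (costs in USD).
#' @seealso [save_parameters()], [default_parameters()]
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  pars <- structure(raw, class = "haic_params")
  pars$settings$max_cycles <- as.integer(pars$settings$max_cycles)
  if (identical(pars$settings$costs_currency, "CNY")) {
    rate <- pars$settings$currency_rate_cny_per_usd
    pars$costs$per_cycle <- lapply(pars$costs$per_cycle, function(v) v / rate)
    pars$costs$one_time <- lapply(pars$costs$one_time, function(v) v / rate)
    for (nm in names(pars$ranges)) {
      if (startsWith(nm, "cost_")) {
        pars$ranges[[nm]]$min <- pars$ranges[[nm]]$min / rate
        pars$ranges[[nm]]$max <- pars$ranges[[nm]]$max / rate
      }
    }
    pars$settings$costs_currency <- "USD"
  }
  validate_parameters(pars)
  pars
}

#' Write a parameter bundle to a YAML or JSON file
#'
#' Serialisation is lossless to 12 significant digits; a save/load round
#' trip reproduces the bundle.
#'
#' @param pars a validated `haic_params` bundle.
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @return Invisibly, `path`.
#' @export
save_parameters <- function(pars, path) {
  validate_parameters(pars)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(pars), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    writeLines(yaml::as.yaml(unclass(pars), precision = 12), path)
  }
  invisible(path)
}
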