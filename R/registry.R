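# Registry mapping sensitivity-analysis parameter ids to locations in the
# bundle. The ids cover every uncertain quantity in the published parameter
# table: costs, utilities, disutilities, SAE incidences per arm, the
# hepatectomy and subsequent-treatment proportions, BSA, the recurrence rate
# and the discount rate. Weibull scale/shape are deliberately absent: the
# source table assigns them no distribution or range.

#' Sensitivity-parameter registry
#'
#' One row per tunable parameter: its id, where it lives in the bundle, and
#' how [sample_parameters()] and [tornado()] treat it. Proportions of the
#' subsequent-treatment mix (`mix_*`) are renormalised against their
#' complement whenever one component is set, so the mix always sums to 1.
#'
#' @return A data frame with columns `param_id`, `path` (list column of
#'   character paths into the bundle) and `group`.
#' @export
param_registry <- function() {
  if (!is.null(.haiccea_cache$registry)) return(.haiccea_cache$registry)
  rows <- list(
    list("utility_pfs", c("utilities", "pfs"), "utility"),
    list("utility_pd", c("utilities", "pd"), "utility"),
    list("cost_sorafenib", c("costs", "per_cycle", "sorafenib"), "cost"),
    list("cost_oxaliplatin", c("costs", "per_cycle", "oxaliplatin"), "cost"),
    list("cost_fluorouracil", c("costs", "per_cycle", "fluorouracil"), "cost"),
    list("cost_leucovorin", c("costs", "per_cycle", "leucovorin"), "cost"),
    list("cost_haic_procedure", c("costs", "per_cycle", "haic_procedure"), "cost"),
    list("cost_hepatectomy", c("costs", "one_time", "hepatectomy"), "cost"),
    list("cost_hospitalization", c("costs", "per_cycle", "hospitalization"), "cost"),
    list("cost_test", c("costs", "per_cycle", "test"), "cost"),
    list("cost_bsc", c("costs", "per_cycle", "bsc"), "cost"),
    list("cost_sae_elevated_alt_ast", c("costs", "one_time", "elevated_alt_ast"), "cost"),
    list("cost_sae_neutropenia", c("costs", "one_time", "neutropenia"), "cost"),
    list("cost_sae_hfs", c("costs", "per_cycle", "hfs"), "cost"),
    list("cost_sae_diarrhea", c("costs", "one_time", "diarrhea"), "cost"),
    list("cost_sae_nausea_vomiting", c("costs", "one_time", "nausea_vomiting"), "cost"),
    list("disutility_neutropenia", c("utilities", "disutility", "neutropenia"), "utility"),
    list("disutility_hfs", c("utilities", "disutility", "hfs"), "utility"),
    list("disutility_diarrhea", c("utilities", "disutility", "diarrhea"), "utility"),
    list("disutility_nausea_vomiting", c("utilities", "disutility", "nausea_vomiting"), "utility"),
    list("hepatectomy_sorahaic", c("strategies", "sorahaic", "hepatectomy_fraction"), "proportion"),
    list("hepatectomy_sorafenib", c("strategies", "sorafenib", "hepatectomy_fraction"), "proportion"),
    list("bsa", c("costs", "bsa_patient"), "other"),
    list("recurrence_rate", c("recurrence", "cumulative_incidence"), "proportion"),
    list("discount_rate", c("settings", "discount_rate_annual"), "other")
  )
  for (arm in c("sorahaic", "sorafenib")) {
    for (s in SAE_TYPES)
      rows[[length(rows) + 1L]] <-
        list(paste0("inc_", arm, "_", s),
             c("strategies", arm, "sae_incidence", s), "proportion")
    for (m in c("sorafenib", "haic", "bsc"))
      rows[[length(rows) + 1L]] <-
        list(paste0("mix_", arm, "_", m),
             c("strategies", arm, "subsequent_mix", m), "proportion")
  }
  reg <- data.frame(
    param_id = vapply(rows, `[[`, "", 1L),
    group = vapply(rows, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
  reg$path <- lapply(rows, `[[`, 2L)
  .haiccea_cache$registry <- reg
  reg
}

get_parameter_value <- function(pars, param_id) {
  reg <- param_registry()
  i <- match(param_id, reg$param_id)
  if (is.na(i)) abort_validation("unknown parameter id", param_id)
  pluck_path(pars, reg$path[[i]])
}

#' Set one sensitivity parameter in a bundle
#'
#' Scalar parameters are assigned directly. Setting one component of a
#' subsequent-treatment mix rescales the other two components so the mix
#' still sums to 1 (the paired yes/no hepatectomy proportion needs no
#' explicit complement: the model uses only the "yes" fraction).
#'
#' @param pars a `haic_params` bundle.
#' @param param_id an id from [param_registry()].
#' @param value new value.
#' @return The modified bundle (not revalidated; callers validate or run).
#' @export
set_parameter_value <- function(pars, param_id, value) {
  reg <- param_registry()
  i <- match(param_id, reg$param_id)
  if (is.na(i)) abort_validation("unknown parameter id", param_id)
  path <- reg$path[[i]]
  if (grepl("^mix_", param_id)) {
    value <- min(max(value, 0), 1)
    arm <- path[2L]
    comp <- path[4L]
    mix <- pars$strategies[[arm]]$subsequent_mix
    others <- setdiff(names(mix), comp)
    osum <- sum(unlist(mix[others]))
    if (osum > 0) {
      for (o in others) mix[[o]] <- mix[[o]] * (1 - value) / osum
    } else {
      for (o in others) mix[[o]] <- (1 - value) / length(others)
    }
    mix[[comp]] <- value
    pars$strategies[[arm]]$subsequent_mix <- mix
    return(pars)
  }
  poke_path(pars, path, value)
}

#' Table of probabilistic-sensitivity-analysis distribution specifications
#'
#' One row per registry parameter, with the base value read from the bundle
#' and the range and distribution family from `pars$ranges`. Parameters
#' without an explicit range default to base +/- 20% (gamma for costs, beta
#' for utilities and proportions, normal otherwise), the fallback the
#' deterministic analysis uses when no published bounds exist.
#'
#' @param pars a `haic_params` bundle.
#' @return Data frame with columns `param_id`, `dist`, `base`, `min`, `max`.
#' @export
psa_specs <- function(pars) {
  reg <- param_registry()
  out <- data.frame(param_id = reg$param_id, dist = NA_character_,
                    base = NA_real_, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(reg))) {
    id <- reg$param_id[i]
    base <- pluck_path(pars, reg$path[[i]])
    r <- pars$ranges[[id]]
    if (is.null(r)) {
      r <- list(min = base * 0.8, max = base * 1.2,
                dist = switch(reg$group[i], cost = "gamma",
                              utility = , proportion = "beta", "normal"))
      if (r$dist == "beta") { r$min <- max(r$min, 0); r$max <- min(r$max, 1) }
    }
    out$dist[i] <- r$dist
    out$base[i] <- base
    out$min[i] <- r$min
    out$max[i] <- r$max
  }
  out
}
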