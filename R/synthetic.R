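# Synthetic "observed" data: noisy mean plasma concentration-time profiles
# with the statistical structure of digitized literature means, study
# metadata tables, and paired DDI datasets.  Everything is generated from
# the simulation model itself, so every downstream stage (evaluation,
# fitting, DFI/DDI workflows) is testable without external data.

#' Residual-error model for synthetic observations
#'
#' Mean profiles carry multiplicative log-normal noise whose log-scale SD
#' is `cv / sqrt(n_subjects)` (the mean-of-n scaling), optionally an
#' additive component, and a lower limit of quantification below which
#' samples are censored (dropped and counted).
#'
#' @param cv Proportional coefficient of variation (fraction, >= 0).
#' @param additive_sd Additive noise SD, ng/mL.
#' @param loq Lower limit of quantification, ng/mL; either a single value
#'   or a named vector per compound (the default reflects typical assay
#'   limits: 1 ng/mL for ketoconazole, 0.25 ng/mL for the low-abundance
#'   metabolite M1).
#' @param seed Integer seed.
#' @param kind Error-model label.
#' @return An `error_model` object.
#' @export
error_model <- function(cv = 0.2, additive_sd = 0,
                        loq = c(ketoconazole = 1, m1 = 0.25), seed = 1,
                        kind = c("proportional-lognormal",
                                 "additive+proportional")) {
  kind <- match.arg(kind)
  if (cv < 0 || any(loq < 0) || additive_sd < 0)
    stop("cv, additive_sd and loq must be >= 0", call. = FALSE)
  structure(list(kind = kind, cv = cv, additive_sd = additive_sd,
                 loq = loq, seed = seed), class = "error_model")
}

#' Define a synthetic study design
#'
#' @param study_id Identifier.
#' @param regimen List of [dose_event()]s.
#' @param sampling_times Sampling times, h.
#' @param n_subjects Number of subjects behind the mean profile (scales the
#'   noise down by `sqrt(n)`).
#' @param compounds Measured compounds; M2 is rejected (it was never
#'   observed in plasma).
#' @param prandial_true True prandial state of the study.
#' @param prandial_declared Declared state (may be `"unknown"`).
#' @return A `synthetic_study` object.
#' @export
synthetic_study <- function(study_id, regimen, sampling_times,
                            n_subjects = 12,
                            compounds = c("ketoconazole", "m1"),
                            prandial_true = "fasted",
                            prandial_declared = prandial_true) {
  if ("m2" %in% compounds)
    stop("M2 cannot be measured: it does not appear in plasma",
         call. = FALSE)
  if (any(sampling_times < 0)) stop("sampling times must be >= 0",
                                    call. = FALSE)
  structure(list(study_id = study_id, regimen = regimen,
                 sampling_times = sort(unique(sampling_times)),
                 n_subjects = n_subjects, compounds = compounds,
                 prandial_true = prandial_true,
                 prandial_declared = prandial_declared),
            class = "synthetic_study")
}

.apply_noise <- function(conc, error, n_subjects) {
  sdlog <- error$cv / sqrt(n_subjects)
  noisy <- conc * exp(stats::rnorm(length(conc), 0, sdlog))
  if (error$additive_sd > 0)
    noisy <- pmax(noisy + stats::rnorm(length(conc), 0,
                                       error$additive_sd /
                                         sqrt(n_subjects)), 0)
  noisy
}

#' Generate synthetic observed profiles for one study
#'
#' Simulates the truth model under the study regimen, samples it at the
#' study's sampling times, applies the error model, and censors values
#' below the limit of quantification.  Deterministic for a fixed error-model
#' seed.
#'
#' @param study A [synthetic_study()].
#' @param error An [error_model()].
#' @param compounds Truth compound list.
#' @param individual Virtual individual.
#' @param scenario Inhibition scenario for the truth simulation.
#' @param ... Further arguments to [simulate_model()].
#' @return List of [observed_profile()]s (one per measured compound), each
#'   with attributes `n_censored` and `truth` (the noise-free values).
#' @export
generate_observed_profiles <- function(study, error = error_model(),
                                       compounds = ketoconazole_compounds(),
                                       individual =
                                         build_reference_individual(),
                                       scenario = "P_M1_M2", ...) {
  stopifnot(inherits(study, "synthetic_study"),
            inherits(error, "error_model"))
  mod <- pbpk_model(individual, compounds, study$regimen,
                    scenario = scenario)
  sim <- simulate_model(mod, t_end = max(study$sampling_times),
                        out_times = study$sampling_times, ...)
  set.seed(error$seed)
  out <- list()
  for (cn in study$compounds) {
    truth <- stats::approx(sim$times, sim$plasma[, cn],
                           xout = study$sampling_times)$y
    noisy <- if (error$cv > 0 || error$additive_sd > 0)
      .apply_noise(truth, error, study$n_subjects) else truth
    lq <- if (!is.null(names(error$loq))) {
      if (cn %in% names(error$loq)) error$loq[[cn]] else min(error$loq)
    } else error$loq
    keep <- noisy >= lq
    prof <- observed_profile(study$study_id, cn,
                             study$sampling_times[keep], noisy[keep],
                             regimen = study$regimen,
                             prandial = study$prandial_declared)
    attr(prof, "n_censored") <- sum(!keep)
    attr(prof, "truth") <- truth[keep]
    out[[cn]] <- prof
  }
  out
}

#' Representative oral dosing design grid
#'
#' Builds a set of synthetic study designs spanning the modeled dosing
#' range: 100--1200 mg single and multiple oral doses, solutions and
#' tablets, fasted and fed states.
#'
#' @param sampling_times Default sampling schedule, h.
#' @param n_subjects Subjects per study.
#' @return List of [synthetic_study()] objects.
#' @export
dose_grid_studies <- function(sampling_times = c(0.5, 1, 1.5, 2, 3, 4, 6, 8,
                                                 12, 24),
                              n_subjects = 12) {
  designs <- list(
    list(dose = 100, n = 1, form = "solution", prandial = "fasted"),
    list(dose = 200, n = 1, form = "tablet", prandial = "fasted"),
    list(dose = 200, n = 1, form = "tablet", prandial = "fed"),
    list(dose = 400, n = 1, form = "tablet", prandial = "fasted"),
    list(dose = 400, n = 1, form = "tablet", prandial = "fed"),
    list(dose = 600, n = 1, form = "tablet", prandial = "fasted"),
    list(dose = 800, n = 1, form = "tablet", prandial = "fed"),
    list(dose = 1200, n = 1, form = "tablet", prandial = "fed"),
    list(dose = 200, n = 4, form = "tablet", prandial = "fed"),
    list(dose = 400, n = 3, form = "capsule", prandial = "fed")
  )
  out <- vector("list", length(designs))
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    reg <- regimen("ketoconazole", d$dose, d$n, interval = 12,
                   formulation = formulation(d$form),
                   prandial_state = d$prandial)
    horizon <- (d$n - 1) * 12
    out[[i]] <- synthetic_study(
      sprintf("S%02d_%dmg_%s_%s", i, d$dose, d$form, d$prandial),
      reg, horizon + sampling_times, n_subjects,
      prandial_true = d$prandial)
  }
  out
}

#' Generate a study metadata table with masked prandial states
#'
#' Emits study-level metadata (dose, doses per day, formulation, observed
#' T_max) with the true prandial state recorded and a fraction of declared
#' states masked as `"unknown"`, for testing the prandial-resolution rules.
#'
#' @param n_studies Number of studies.
#' @param missing_state_fraction Fraction of studies whose declared state
#'   is masked.
#' @param seed Integer seed.
#' @return Data frame with columns `study_id`, `dose`, `doses_per_day`,
#'   `formulation`, `observed_tmax`, `true_state`, `declared_state`.
#' @export
generate_study_table <- function(n_studies, missing_state_fraction = 0.3,
                                 seed = 1) {
  if (missing_state_fraction < 0 || missing_state_fraction > 1)
    stop("missing_state_fraction must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  dose <- sample(c(100, 200, 400, 600, 800, 1200), n_studies, TRUE)
  dpd <- sample(1:2, n_studies, TRUE, prob = c(0.7, 0.3))
  form <- sample(c("tablet", "solution"), n_studies, TRUE,
                 prob = c(0.8, 0.2))
  true_state <- ifelse(dpd > 1 | dose >= 800, "fed",
                       sample(c("fasted", "fed"), n_studies, TRUE,
                              prob = c(0.7, 0.3)))
  tmax <- ifelse(true_state == "fed", stats::runif(n_studies, 2.5, 5),
                 stats::runif(n_studies, 1, 2))
  masked <- stats::runif(n_studies) < missing_state_fraction
  declared <- ifelse(masked, "unknown", true_state)
  data.frame(study_id = sprintf("T%03d", seq_len(n_studies)),
             dose = dose, doses_per_day = dpd, formulation = form,
             observed_tmax = round(tmax, 2), true_state = true_state,
             declared_state = declared, stringsAsFactors = FALSE)
}

#' Generate a paired (reference/effect) synthetic DDI dataset
#'
#' Simulates the victim drug with and without the perpetrator regimen of a
#' DDI scenario, samples the victim plasma profile in both arms and applies
#' the error model.  The noise-free profiles reproduce the truth
#' interaction ratio exactly.
#'
#' @param scen A [ddi_scenario()].
#' @param error An [error_model()].
#' @param sampling_times Victim sampling times relative to the victim dose,
#'   h.
#' @param individual Virtual individual.
#' @param ... Further arguments to [simulate_model()].
#' @return List with `reference` and `effect` [observed_profile()]s, and
#'   `truth_ratio` (noise-free AUC_last effect/reference).
#' @export
generate_ddi_dataset <- function(scen, error = error_model(),
                                 sampling_times = c(0.5, 1, 2, 3, 4, 6, 8,
                                                    12, 24),
                                 individual = build_reference_individual(),
                                 ...) {
  stopifnot(inherits(scen, "ddi_scenario"))
  victim <- scen$victim
  vstart <- min(vapply(scen$victim_regimen, `[[`, numeric(1), "time"))
  abs_times <- vstart + sampling_times
  ref_mod <- pbpk_model(individual, list(victim), scen$victim_regimen,
                        scenario = "none")
  ref <- simulate_model(ref_mod, t_end = max(abs_times),
                        out_times = abs_times, ...)
  cmps <- c(stats::setNames(list(victim), victim$name),
            ketoconazole_compounds())
  eff_mod <- pbpk_model(individual, cmps,
                        c(scen$victim_regimen, scen$perpetrator_regimen),
                        scenario = scen$scenario)
  eff <- simulate_model(eff_mod, t_end = max(abs_times),
                        out_times = abs_times, ...)
  tr_ref <- stats::approx(ref$times, ref$plasma[, victim$name],
                          xout = abs_times)$y
  tr_eff <- stats::approx(eff$times, eff$plasma[, victim$name],
                          xout = abs_times)$y
  truth_ratio <- auc_last(abs_times, tr_eff) / auc_last(abs_times, tr_ref)
  set.seed(error$seed)
  mk <- function(truth, arm) {
    noisy <- if (error$cv > 0 || error$additive_sd > 0)
      .apply_noise(truth, error, 12) else truth
    lq <- if (!is.null(names(error$loq))) {
      if (victim$name %in% names(error$loq)) error$loq[[victim$name]]
      else min(error$loq)
    } else error$loq
    keep <- noisy >= lq
    prof <- observed_profile(paste0("ddi_", arm), victim$name,
                             abs_times[keep], noisy[keep],
                             regimen = if (arm == "effect")
                               c(scen$victim_regimen,
                                 scen$perpetrator_regimen)
                             else scen$victim_regimen)
    attr(prof, "truth") <- truth[keep]
    prof
  }
  list(reference = mk(tr_ref, "reference"), effect = mk(tr_eff, "effect"),
       truth_ratio = truth_ratio)
}
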