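# DFI and DDI study orchestration: paired fasted/fed runs, victim +/-
# perpetrator runs under scenarios P / P+M1 / P+M1+M2, ratio computation
# and reporting.

#' Load the ketoconazole parent--metabolite compound set
#'
#' @return Named list of [compound()] objects `ketoconazole`, `m1`, `m2`.
#' @export
ketoconazole_compounds <- function() {
  list(ketoconazole = load_compound("ketoconazole"),
       m1 = load_compound("m1"),
       m2 = load_compound("m2"))
}

#' Load a victim-drug fixture
#'
#' The victim models shipped with the package are synthetic simplified
#' surrogates (single CYP3A4 elimination or P-gp efflux in the whole-body
#' structure), intended to exercise the interaction machinery; they are not
#' published victim PBPK models.
#'
#' @param name One of `"alfentanil"`, `"alprazolam"`, `"midazolam"`,
#'   `"triazolam"`, `"digoxin"`.
#' @return A [compound()] object.
#' @export
load_victim <- function(name = c("midazolam", "alprazolam", "alfentanil",
                                 "triazolam", "digoxin")) {
  name <- match.arg(name)
  load_compound(paste0(name, "_fixture"))
}

#' Simulate a ketoconazole regimen
#'
#' Convenience wrapper: builds the parent--metabolite model on the
#' reference individual and simulates an oral ketoconazole regimen.
#'
#' @param dose Dose per administration, mg.
#' @param n_doses,interval Number of doses and dosing interval (h).
#' @param formulation A [formulation()] (default tablet).
#' @param prandial `"fasted"` or `"fed"`.
#' @param t_end Simulation end, h.
#' @param scenario Autoinhibition scenario (see [scenario_inhibitors()]).
#' @param individual Virtual individual (default reference adult).
#' @param ... Further arguments to [simulate_model()].
#' @return A `pbpk_result`.
#' @export
simulate_ketoconazole <- function(dose, n_doses = 1, interval = 24,
                                  formulation = ketopbpk::formulation("tablet"),
                                  prandial = "fasted", t_end = 48,
                                  scenario = "P_M1_M2",
                                  individual = build_reference_individual(),
                                  ...) {
  cmps <- ketoconazole_compounds()
  reg <- regimen("ketoconazole", dose, n_doses, interval,
                 formulation = formulation, prandial_state = prandial)
  mod <- pbpk_model(individual, cmps, reg, scenario = scenario)
  simulate_model(mod, t_end, ...)
}

#' Run a paired fasted/fed drug--food interaction study
#'
#' Simulates the identical ketoconazole regimen under fasted (reference)
#' and fed (effect) conditions and computes the DFI ratios
#' `PK_effect / PK_reference` for AUC_last and C_max over a common
#' sampling window.
#'
#' @param dose Dose per administration, mg.
#' @param formulation A [formulation()].
#' @param n_doses,interval Regimen shape.
#' @param t_end Observation window end, h.
#' @param observed Optional named list of observed DFI ratios
#'   (`AUC_last`, `C_max`) against which Guest-limit and two-fold verdicts
#'   are evaluated.
#' @param ... Further arguments to [simulate_model()].
#' @return A `study_report` list: per-arm PK, `ratios`, and (if observed
#'   ratios were given) `verdicts`.
#' @export
run_dfi_study <- function(dose, formulation = ketopbpk::formulation("tablet"),
                          n_doses = 1, interval = 24, t_end = 48,
                          observed = NULL, ...) {
  if (dose <= 0) stop("dose must be > 0", call. = FALSE)
  arms <- lapply(c(reference = "fasted", effect = "fed"), function(p)
    simulate_ketoconazole(dose, n_doses, interval, formulation,
                          prandial = p, t_end = t_end, ...))
  pk <- lapply(arms, function(r)
    pk_parameters(r$times, r$plasma[, "ketoconazole"]))
  ratios <- list(
    AUC_last = interaction_ratio(pk$effect$AUC_last, pk$reference$AUC_last,
                                 "AUC_last"),
    C_max = interaction_ratio(pk$effect$C_max, pk$reference$C_max, "C_max"))
  rep <- list(kind = "DFI", dose = dose, arms = pk, ratios = ratios,
              results = arms)
  if (!is.null(observed)) rep$verdicts <- .ratio_verdicts(ratios, observed)
  class(rep) <- "study_report"
  rep
}

.ratio_verdicts <- function(ratios, observed) {
  out <- list()
  for (m in intersect(names(ratios), names(observed))) {
    gl <- guest_limits(observed[[m]])
    pred <- ratios[[m]]$ratio
    out[[m]] <- list(observed = observed[[m]], predicted = pred,
                     guest = unname(pred >= gl["lower"] & pred <= gl["upper"]),
                     twofold = within_twofold(pred, observed[[m]]),
                     guest_limits = gl)
  }
  out
}

#' Define a DDI scenario
#'
#' @param victim Victim compound name (fixture) or a [compound()] object.
#' @param scenario Perpetrator scenario: `"P"`, `"P_M1"` or `"P_M1_M2"`.
#' @param perpetrator_regimen List of ketoconazole [dose_event()]s.
#' @param victim_regimen List of victim [dose_event()]s.
#' @return A `ddi_scenario` list; `dosing_gap` (h) is the time from the
#'   perpetrator dose immediately preceding the first victim dose (negative
#'   when the victim is dosed first).
#' @export
ddi_scenario <- function(victim, scenario = "P_M1_M2",
                         perpetrator_regimen, victim_regimen) {
  if (is.character(victim)) victim <- load_victim(victim)
  scenario <- match.arg(scenario, c("P", "P_M1", "P_M1_M2"))
  vt <- min(vapply(victim_regimen, `[[`, numeric(1), "time"))
  pt <- vapply(perpetrator_regimen, `[[`, numeric(1), "time")
  gap <- if (any(pt <= vt)) vt - max(pt[pt <= vt]) else vt - min(pt)
  structure(list(victim = victim, scenario = scenario,
                 perpetrator_regimen = perpetrator_regimen,
                 victim_regimen = victim_regimen, dosing_gap = gap),
            class = "ddi_scenario")
}

#' Run a drug--drug interaction study
#'
#' Simulates the victim drug alone (reference) and together with the
#' ketoconazole perpetrator regimen under one or more inhibition scenarios,
#' and computes the DDI ratios of AUC_last and C_max of the victim over the
#' window starting at the first victim dose.  The reference arm uses the
#' bit-identical victim regimen with the perpetrator dose removed.
#'
#' @param scen A [ddi_scenario()]; its `scenario` field is ignored when
#'   `scenarios` is given explicitly.
#' @param scenarios Character vector of inhibition scenarios to simulate.
#' @param window Observation window after the first victim dose, h.
#' @param observed Optional observed DDI ratios (named list `AUC_last`,
#'   `C_max`) for Guest/two-fold verdicts.
#' @param individual Virtual individual.
#' @param ... Further arguments to [simulate_model()].
#' @return A `study_report` with per-scenario ratios and verdicts.
#' @export
run_ddi_study <- function(scen, scenarios = scen$scenario, window = 24,
                          observed = NULL,
                          individual = build_reference_individual(), ...) {
  stopifnot(inherits(scen, "ddi_scenario"))
  victim <- scen$victim
  vstart <- min(vapply(scen$victim_regimen, `[[`, numeric(1), "time"))
  t_end <- vstart + window
  vic_pk <- function(res) {
    keep <- res$times >= vstart
    pk_parameters(res$times[keep], res$plasma[keep, victim$name])
  }
  # reference: victim alone, identical victim regimen
  ref_mod <- pbpk_model(individual, list(victim), scen$victim_regimen,
                        scenario = "none")
  ref <- simulate_model(ref_mod, t_end, ...)
  pk_ref <- vic_pk(ref)

  cmps <- c(stats::setNames(list(victim), victim$name),
            ketoconazole_compounds())
  doses <- c(scen$victim_regimen, scen$perpetrator_regimen)
  arms <- list()
  for (sc in scenarios) {
    mod <- pbpk_model(individual, cmps, doses, scenario = sc)
    res <- simulate_model(mod, t_end, ...)
    pk <- vic_pk(res)
    ratios <- list(
      AUC_last = interaction_ratio(pk$AUC_last, pk_ref$AUC_last, "AUC_last"),
      C_max = interaction_ratio(pk$C_max, pk_ref$C_max, "C_max"))
    arm <- list(scenario = sc, pk = pk, ratios = ratios, result = res)
    if (!is.null(observed)) arm$verdicts <- .ratio_verdicts(ratios, observed)
    arms[[sc]] <- arm
  }
  structure(list(kind = "DDI", victim = victim$name,
                 dosing_gap = scen$dosing_gap,
                 reference_pk = pk_ref, reference = ref, arms = arms,
                 regimen_hash = .regimen_hash(scen$victim_regimen)),
            class = "study_report")
}

# stable fingerprint of a regimen (used to assert that reference and effect
# arms share the victim regimen bit-for-bit)
.regimen_hash <- function(reg) {
  paste(vapply(reg, function(d)
    sprintf("%s|%.10g|%.10g|%s|%s", d$compound, d$dose, d$time,
            d$formulation$kind, d$prandial_state), character(1)),
    collapse = ";")
}

#' @export
print.study_report <- function(x, ...) {
  if (x$kind == "DFI") {
    cat(sprintf("<study_report> DFI, %g mg: AUC_last ratio %.2f, C_max ratio %.2f\n",
                x$dose, x$ratios$AUC_last$ratio, x$ratios$C_max$ratio))
  } else {
    cat(sprintf("<study_report> DDI, victim %s, gap %.1f h\n",
                x$victim, x$dosing_gap))
    for (a in x$arms)
      cat(sprintf("  %-9s AUC ratio %.2f, Cmax ratio %.2f\n", a$scenario,
                  a$ratios$AUC_last$ratio, a$ratios$C_max$ratio))
  }
  invisible(x)
}

#' Sweep DDI scenarios over dosing time gaps
#'
#' Runs [run_ddi_study()] for every combination of dosing gap and
#' inhibition scenario and tabulates the victim AUC_last and C_max ratios.
#' The perpetrator is dosed at time 0 (single dose by default) and the
#' victim at `gap` hours later (clamped at 0 for negative gaps, in which
#' case the perpetrator is delayed instead).
#'
#' @param victim Victim name or [compound()].
#' @param gaps Numeric vector of dosing gaps, h.
#' @param scenarios Inhibition scenarios.
#' @param perp_dose Perpetrator dose, mg.
#' @param perp_n,perp_interval Perpetrator regimen shape.
#' @param victim_dose Victim dose, mg.
#' @param window Observation window after the victim dose, h.
#' @param ... Further arguments to [simulate_model()].
#' @return Data frame with columns `gap`, `scenario`, `auc_ratio`,
#'   `cmax_ratio`.
#' @export
scenario_sweep <- function(victim, gaps, scenarios = c("P", "P_M1", "P_M1_M2"),
                           perp_dose = 400, perp_n = 1, perp_interval = 24,
                           victim_dose = 7.5, window = 24, ...) {
  if (is.character(victim)) victim <- load_victim(victim)
  rows <- list()
  for (gap in gaps) {
    perp_start <- max(0, -gap)
    vic_time <- perp_start + (perp_n - 1) * perp_interval + gap
    perp_reg <- regimen("ketoconazole", perp_dose, perp_n, perp_interval,
                        start = perp_start,
                        formulation = formulation("tablet"))
    vic_reg <- regimen(victim$name, victim_dose, 1, start = vic_time)
    scen <- ddi_scenario(victim, "P_M1_M2", perp_reg, vic_reg)
    rep <- run_ddi_study(scen, scenarios = scenarios, window = window, ...)
    for (a in rep$arms)
      rows[[length(rows) + 1]] <- data.frame(
        gap = gap, scenario = a$scenario,
        auc_ratio = a$ratios$AUC_last$ratio,
        cmax_ratio = a$ratios$C_max$ratio)
  }
  if (!length(rows))
    return(data.frame(gap = numeric(0), scenario = character(0),
                      auc_ratio = numeric(0), cmax_ratio = numeric(0)))
  do.call(rbind, rows)
}
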