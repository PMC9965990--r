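# Parameter estimation against observed plasma concentration-time profiles
# (Levenberg-Marquardt or seeded Monte-Carlo search) and local sensitivity
# analysis.

#' Define an observed plasma profile
#'
#' @param study_id Study identifier (profiles sharing an id share a
#'   regimen).
#' @param compound Measured compound name.
#' @param times Sampling times, h (strictly increasing).
#' @param conc Mean concentrations, ng/mL (>= 0).
#' @param regimen List of [dose_event()]s that generated the profile.
#' @param sd Optional standard deviations, ng/mL.
#' @param prandial Declared prandial state.
#' @return An `observed_profile` object.
#' @export
observed_profile <- function(study_id, compound, times, conc,
                             regimen = NULL, sd = NULL,
                             prandial = "unknown") {
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  structure(list(study_id = study_id, compound = compound,
                 times = times, conc = conc, sd = sd,
                 regimen = regimen, prandial = prandial),
            class = "observed_profile")
}

# Apply free-parameter values to a compound list.  `free` rows address
# either a process parameter (protein given: k_cat, K_M, CL_spec) or a
# compound-level parameter (logP, fu, ...).
.apply_params <- function(compounds, free, values) {
  for (i in seq_len(nrow(free))) {
    cn <- free$compound[i]
    if (is.null(compounds[[cn]]))
      stop("free parameter addresses unknown compound: ", cn, call. = FALSE)
    if (!is.na(free$protein[i]) && nzchar(free$protein[i])) {
      hit <- FALSE
      for (k in seq_along(compounds[[cn]]$processes)) {
        if (compounds[[cn]]$processes[[k]]$protein == free$protein[i]) {
          compounds[[cn]]$processes[[k]][[free$param[i]]] <- values[i]
          hit <- TRUE
        }
      }
      if (!hit)
        stop("no ", free$protein[i], " process on ", cn, call. = FALSE)
    } else {
      compounds[[cn]][[free$param[i]]] <- values[i]
    }
  }
  compounds
}

# Simulate every study once and return log10 residuals over all profiles.
.fit_residuals <- function(values, free, studies, compounds, individual,
                           scenario, rtol, atol, floor = 1e-4) {
  cmps <- .apply_params(compounds, free, values)
  res <- numeric(0)
  for (sd in studies) {
    tmax <- max(vapply(sd$profiles, function(p) max(p$times), numeric(1)))
    mod <- pbpk_model(individual, cmps, sd$regimen, scenario = scenario)
    sim <- simulate_model(mod, t_end = tmax, rtol = rtol, atol = atol,
                          out_times = sort(unique(unlist(
                            lapply(sd$profiles, `[[`, "times")))))
    for (p in sd$profiles) {
      pred <- stats::approx(sim$times, sim$plasma[, p$compound],
                            xout = p$times)$y
      keep <- p$conc > 0
      res <- c(res, log10(pmax(pred[keep], floor)) - log10(p$conc[keep]))
    }
  }
  res
}

.group_studies <- function(observed) {
  ids <- vapply(observed, `[[`, character(1), "study_id")
  lapply(split(observed, ids), function(ps) {
    reg <- NULL
    for (p in ps) if (!is.null(p$regimen)) { reg <- p$regimen; break }
    if (is.null(reg))
      stop("study ", ps[[1]]$study_id, " carries no regimen", call. = FALSE)
    list(regimen = reg, profiles = ps)
  })
}

#' Fit model parameters to observed profiles
#'
#' Minimizes the pooled sum of squared log10-concentration residuals over
#' all observed profiles simultaneously, either by bounded
#' Levenberg--Marquardt least squares or by a seeded uniform Monte-Carlo
#' search followed by a Levenberg--Marquardt polish.
#'
#' @param free Data frame with columns `compound`, `protein` (`NA` for
#'   compound-level parameters), `param`, `lower`, `upper`, `start`.
#' @param observed List of [observed_profile()]s; profiles sharing a
#'   `study_id` are simulated together under that study's regimen.
#' @param method `"LevenbergMarquardt"` or `"MonteCarlo"`.
#' @param seed Integer seed controlling the Monte-Carlo draws.
#' @param n_mc Number of Monte-Carlo samples before the polish.
#' @param compounds Compound list to start from.
#' @param individual Virtual individual.
#' @param scenario Inhibition scenario used during fitting.
#' @param rtol,atol Solver tolerances used inside the objective.
#' @param maxiter Maximum Levenberg--Marquardt iterations.
#' @return A list with `estimates` (named vector), `objective` (final sum
#'   of squares), `trace` (objective per accepted evaluation),
#'   `converged`, and `method`.
#' @export
fit_parameters <- function(free, observed,
                           method = c("LevenbergMarquardt", "MonteCarlo"),
                           seed = 1, n_mc = 100,
                           compounds = ketoconazole_compounds(),
                           individual = build_reference_individual(),
                           scenario = "P_M1_M2",
                           rtol = 1e-6, atol = 1e-9, maxiter = 30) {
  method <- match.arg(method)
  stopifnot(is.data.frame(free),
            all(c("compound", "param", "lower", "upper", "start") %in%
                  names(free)))
  if (!"protein" %in% names(free)) free$protein <- NA_character_
  studies <- .group_studies(observed)
  trace <- numeric(0)
  fn <- function(v) {
    r <- .fit_residuals(v, free, studies, compounds, individual, scenario,
                        rtol, atol)
    trace <<- c(trace, sum(r^2))
    r
  }
  start <- free$start
  if (method == "MonteCarlo") {
    set.seed(seed)
    draws <- matrix(stats::runif(n_mc * nrow(free), free$lower, free$upper),
                    ncol = nrow(free), byrow = TRUE)
    sse <- apply(draws, 1, function(v) sum(fn(v)^2))
    start <- draws[which.min(sse), ]
  }
  # finite-difference steps must clear the ODE solver's noise floor, so a
  # relative Jacobian step of ~1e-3 (epsfcn = 1e-6) is used instead of the
  # machine-precision default
  fit <- try(minpack.lm::nls.lm(
    par = start, lower = free$lower, upper = free$upper, fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                         epsfcn = 1e-6)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    warning("optimization failed; returning start values")
    est <- start; obj <- sum(fn(start)^2); conv <- FALSE
  } else {
    est <- fit$par
    obj <- fit$deviance
    conv <- fit$info %in% 1:4
    if (!conv) warning("optimizer did not report convergence (info = ",
                       fit$info, ")")
  }
  names(est) <- paste(free$compound,
                      ifelse(is.na(free$protein), "", free$protein),
                      free$param, sep = ".")
  list(estimates = est, objective = obj, trace = trace,
       converged = conv, method = method)
}

#' Local sensitivity of exposure to one parameter
#'
#' Normalized local sensitivity coefficient
#' `S = (dAUC / AUC) / (dp / p)` by central finite difference around the
#' current parameter value.
#'
#' @param parameter One-row data frame (or list) with `compound`, `protein`
#'   (`NA` for compound-level) and `param`.
#' @param doses Regimen (list of [dose_event()]s).
#' @param output_compound Compound whose plasma AUC_last is the output.
#' @param relative_perturbation Relative step (default 0.1).
#' @param t_end Simulation horizon, h.
#' @param compounds,individual,scenario,rtol,atol As in
#'   [fit_parameters()].
#' @return Sensitivity coefficient (unitless); `NA` with a warning if a
#'   perturbed simulation fails.
#' @export
local_sensitivity <- function(parameter, doses,
                              output_compound = "ketoconazole",
                              relative_perturbation = 0.1, t_end = 48,
                              compounds = ketoconazole_compounds(),
                              individual = build_reference_individual(),
                              scenario = "P_M1_M2",
                              rtol = 1e-6, atol = 1e-9) {
  par <- as.data.frame(parameter, stringsAsFactors = FALSE)
  if (!"protein" %in% names(par)) par$protein <- NA_character_
  base_val <- if (!is.na(par$protein) && nzchar(par$protein)) {
    v <- NULL
    for (p in compounds[[par$compound]]$processes)
      if (p$protein == par$protein) v <- p[[par$param]]
    v
  } else compounds[[par$compound]][[par$param]]
  if (is.null(base_val))
    stop("parameter not found on compound", call. = FALSE)
  auc_at <- function(val) {
    cmps <- .apply_params(compounds, par, val)
    mod <- pbpk_model(individual, cmps, doses, scenario = scenario)
    sim <- simulate_model(mod, t_end, grid = 0.25, rtol = rtol, atol = atol)
    auc_last(sim$times, sim$plasma[, output_compound])
  }
  out <- try({
    a0 <- auc_at(base_val)
    ap <- auc_at(base_val * (1 + relative_perturbation))
    am <- auc_at(base_val * (1 - relative_perturbation))
    ((ap - am) / a0) / (2 * relative_perturbation)
  }, silent = TRUE)
  if (inherits(out, "try-error")) {
    warning("sensitivity undefined: simulation failed at perturbed value")
    return(NA_real_)
  }
  out
}

#' Rank local sensitivities for a set of parameters
#'
#' @param parameters Data frame of parameter rows (see
#'   [local_sensitivity()]).
#' @param ... Passed to [local_sensitivity()].
#' @return The input with a `sensitivity` column, ordered by decreasing
#'   absolute sensitivity.
#' @export
sensitivity_analysis <- function(parameters, ...) {
  parameters$sensitivity <- vapply(seq_len(nrow(parameters)), function(i)
    local_sensitivity(parameters[i, , drop = FALSE], ...), numeric(1))
  parameters[order(-abs(parameters$sensitivity)), ]
}
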