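# Non-compartmental PK metrics and model-evaluation statistics.

#' Area under the curve to the last measurement
#'
#' Linear trapezoidal rule from the first to the last sampling time.
#'
#' @param times Sampling times, h (strictly increasing).
#' @param conc Concentrations, ng/mL.
#' @return AUC_last in ng*h/mL.
#' @examples
#' auc_last(c(0, 1, 2), c(0, 2, 0))  # 2
#' @export
auc_last <- function(times, conc) {
  if (length(times) < 2)
    stop("at least two points are required for AUC_last", call. = FALSE)
  if (length(times) != length(conc))
    stop("times and conc must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  sum(diff(times) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
}

#' Maximum concentration and its time
#'
#' First occurrence wins on ties.  An all-zero profile returns
#' `c(cmax = 0, tmax = 0)` with attribute `degenerate = TRUE`.
#'
#' @param times Sampling times, h.
#' @param conc Concentrations, ng/mL.
#' @return Named vector `c(cmax, tmax)`.
#' @export
cmax_tmax <- function(times, conc) {
  if (length(times) < 1) stop("empty profile", call. = FALSE)
  if (all(conc == 0)) {
    out <- c(cmax = 0, tmax = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  i <- which.max(conc)
  c(cmax = conc[i], tmax = times[i])
}

#' Terminal half-life by log-linear regression
#'
#' `ln(2) / lambda_z` with the terminal slope `lambda_z` estimated by
#' least squares on log concentrations over the last `n_terminal` points
#' after the observed maximum.
#'
#' @param times Sampling times, h.
#' @param conc Concentrations (positive over the terminal phase).
#' @param n_terminal Number of terminal points used (>= 3).
#' @return Half-life in h, or `NA` (with a warning) when the terminal
#'   points are non-positive or non-decaying.
#' @export
terminal_half_life <- function(times, conc, n_terminal = 4) {
  if (n_terminal < 3) stop("n_terminal must be >= 3", call. = FALSE)
  i_max <- which.max(conc)
  idx <- seq(max(i_max + 1, length(conc) - n_terminal + 1), length(conc))
  tt <- times[idx]; cc <- conc[idx]
  if (length(idx) < 3 || any(cc <= 0)) {
    warning("terminal phase undefined (non-positive or too few points)")
    return(NA_real_)
  }
  lz <- -stats::coef(stats::lm(log(cc) ~ tt))[["tt"]]
  if (lz <= 0) {
    warning("terminal phase not decaying")
    return(NA_real_)
  }
  log(2) / lz
}

#' Mean relative deviation of predicted concentrations
#'
#' `MRD = 10^x` with `x` the root mean square of
#' `log10(predicted) - log10(observed)` over all pairs.  Values at or below
#' zero are rejected; censored observations must be excluded beforehand.
#'
#' @param observed Observed concentrations (> 0).
#' @param predicted Predicted concentrations (> 0), same length.
#' @return MRD (>= 1).
#' @examples
#' mrd(c(10, 100), c(100, 10))  # 10
#' @export
mrd <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0)
    stop("observed and predicted must be non-empty and equal length",
         call. = FALSE)
  bad <- which(observed <= 0 | predicted <= 0)
  if (length(bad))
    stop("non-positive concentration at index ", bad[1], call. = FALSE)
  10^sqrt(mean((log10(predicted) - log10(observed))^2))
}

#' Geometric mean fold error of PK parameters
#'
#' `GMFE = 10^x` with `x` the mean absolute `log10(predicted/observed)`
#' over studies.
#'
#' @param observed Observed PK values (> 0).
#' @param predicted Predicted PK values (> 0), same length.
#' @return GMFE (>= 1).
#' @examples
#' gmfe(c(100, 100), c(200, 50))  # 2
#' @export
gmfe <- function(observed, predicted) {
  if (length(observed) == 0)
    stop("empty comparison", call. = FALSE)
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  if (any(observed <= 0) || any(predicted <= 0))
    stop("PK values must be positive", call. = FALSE)
  10^mean(abs(log10(predicted / observed)))
}

#' Interaction (effect/reference) PK ratio
#'
#' The drug--food or drug--drug interaction ratio of a PK parameter:
#' the effect-arm value divided by the reference-arm value.
#'
#' @param effect_pk PK value under the interaction (fed arm, or victim with
#'   perpetrator).
#' @param reference_pk PK value of the control arm (> 0).
#' @param metric Label carried through (`"AUC_last"` or `"C_max"`).
#' @return A list with `metric`, `effect`, `reference` and `ratio`.
#' @export
interaction_ratio <- function(effect_pk, reference_pk,
                              metric = c("AUC_last", "C_max")) {
  metric <- match.arg(metric)
  if (!is.numeric(reference_pk) || reference_pk <= 0)
    stop("reference PK value must be positive", call. = FALSE)
  list(metric = metric, effect = effect_pk, reference = reference_pk,
       ratio = effect_pk / reference_pk)
}

#' Guest et al. acceptance limits for interaction ratios
#'
#' Ratio-dependent acceptance band for a predicted interaction ratio given
#' the observed ratio: with `R` the observed ratio folded to be >= 1, the
#' limit factor is `L = (variability + 2 (R - 1)) / R`, and the band is
#' `(observed / L, observed * L)`.  At `R = 1` the band is
#' `(1/variability, variability)`; as `R` grows it approaches the classical
#' two-fold criterion.
#'
#' @param observed_ratio Observed interaction ratio (> 0).
#' @param variability Fold-variability parameter (default 1.25).
#' @return Named vector `c(lower, upper)`.
#' @examples
#' guest_limits(1)     # (0.8, 1.25)
#' @export
guest_limits <- function(observed_ratio, variability = 1.25) {
  if (observed_ratio <= 0)
    stop("observed_ratio must be positive", call. = FALSE)
  R <- if (observed_ratio >= 1) observed_ratio else 1 / observed_ratio
  L <- (variability + 2 * (R - 1)) / R
  c(lower = observed_ratio / L, upper = observed_ratio * L)
}

#' Two-fold acceptance criterion
#'
#' @param predicted Predicted value (> 0).
#' @param observed Observed value (> 0).
#' @return `TRUE` iff the ratio lies in `[0.5, 2]` (boundaries included).
#' @export
within_twofold <- function(predicted, observed) {
  if (predicted <= 0 || observed <= 0)
    stop("values must be positive", call. = FALSE)
  r <- predicted / observed
  r >= 0.5 && r <= 2
}

#' Non-compartmental PK parameters of a profile
#'
#' Convenience wrapper returning AUC_last, C_max, T_max and (when the
#' terminal phase is estimable) the terminal half-life.
#'
#' @param times Sampling times, h.
#' @param conc Concentrations, ng/mL.
#' @param n_terminal Terminal points for the half-life fit.
#' @return Named list `AUC_last`, `C_max`, `T_max`, `t_half`.
#' @export
pk_parameters <- function(times, conc, n_terminal = 4) {
  ct <- cmax_tmax(times, conc)
  th <- suppressWarnings(terminal_half_life(times, conc, n_terminal))
  list(AUC_last = auc_last(times, conc),
       C_max = unname(ct["cmax"]), T_max = unname(ct["tmax"]),
       t_half = th)
}
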