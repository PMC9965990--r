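# Gastrointestinal tract: segment geometry, formulations, prandial-state
# rules and particle dissolution.

.GI_SEGMENTS <- c("stomach", "duodenum", "upper jejunum", "lower jejunum",
                  "upper ileum", "lower ileum", "caecum", "colon")

#' Default gastrointestinal tract
#'
#' An eight-segment transit model (stomach, four small-intestinal segments
#' plus duodenum, caecum, colon) with luminal volumes, segment pH, effective
#' absorptive surface areas (including villous amplification) and mean
#' transit times.  The gastric emptying time (GET) and the gastric pH depend
#' on the prandial state: 15 min / pH 2.0 fasted versus 45 min / pH 3.0 fed
#' (meal buffering transiently raises gastric pH; the fed value is the
#' average over the prolonged emptying phase).
#'
#' @param prandial `"fasted"` or `"fed"`; sets GET and stomach pH.
#' @return An object of class `gi_tract`: a data frame of segments plus the
#'   `GET` attribute in minutes.
#' @export
default_gi_tract <- function(prandial = c("fasted", "fed")) {
  prandial <- match.arg(prandial)
  seg <- data.frame(
    segment = .GI_SEGMENTS,
    volume = c(0.25, 0.05, 0.10, 0.10, 0.10, 0.10, 0.05, 0.20),   # L
    pH = c(if (prandial == "fed") 3.0 else 2.0,
           6.0, 6.2, 6.4, 6.6, 6.9, 6.4, 7.0),
    surface_area = c(3e2, 6e4, 1.2e5, 1.2e5, 9e4, 7e4, 8e3, 1.5e4), # cm^2
    transit = c(if (prandial == "fed") 45 else 15,
                15, 30, 45, 45, 60, 90, 720),                       # min
    stringsAsFactors = FALSE
  )
  structure(list(segments = seg,
                 GET = seg$transit[1],
                 prandial = prandial),
            class = "gi_tract")
}

#' Create a formulation
#'
#' Oral solutions are treated as immediately dissolved; tablets and capsules
#' carry a discretized particle-size distribution.  The default solid
#' distribution is log-normal in particle radius with a median of 300 um and
#' a geometric standard deviation of 2, discretized into mass-equal-width
#' log bins; the large effective (hydrodynamic) radii reproduce tablet
#' dissolution half-times of tens of minutes in acidic media.
#'
#' @param kind `"solution"`, `"tablet"` or `"capsule"`.
#' @param median_radius Median particle radius, um (solids only).
#' @param gsd Geometric standard deviation of the radius distribution.
#' @param n_bins Number of discretization bins.
#' @param density Particle density, g/cm^3.
#' @return An object of class `formulation` with a `particle_bins` data
#'   frame (`radius` um, `mass_fraction`).
#' @export
formulation <- function(kind = c("tablet", "capsule", "solution"),
                        median_radius = 300, gsd = 2, n_bins = 10,
                        density = 1.2) {
  kind <- match.arg(kind)
  if (kind == "solution") {
    bins <- data.frame(radius = 1e-3, mass_fraction = 1)
  } else {
    if (median_radius <= 0 || gsd < 1)
      stop("median_radius must be positive and gsd >= 1", call. = FALSE)
    if (gsd == 1 || n_bins == 1) {
      bins <- data.frame(radius = median_radius, mass_fraction = 1)
    } else {
      q <- seq(0, 1, length.out = n_bins + 1)
      q[1] <- 0.005; q[n_bins + 1] <- 0.995
      edges <- stats::qlnorm(q, meanlog = log(median_radius),
                             sdlog = log(gsd))
      mids <- sqrt(edges[-1] * edges[-(n_bins + 1)])
      frac <- diff(stats::plnorm(edges, log(median_radius), log(gsd)))
      bins <- data.frame(radius = mids, mass_fraction = frac / sum(frac))
    }
  }
  structure(list(kind = kind, particle_bins = bins, density = density),
            class = "formulation")
}

#' Create a dose event
#'
#' @param compound Compound name.
#' @param dose Dose in mg (> 0).
#' @param time Dosing time in hours (>= 0).
#' @param formulation A [formulation()]; defaults to an oral solution.
#' @param prandial_state `"fasted"`, `"fed"` or `"unknown"`.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(compound, dose, time = 0,
                       formulation = ketopbpk::formulation("solution"),
                       prandial_state = c("fasted", "fed", "unknown")) {
  prandial_state <- match.arg(prandial_state)
  if (dose <= 0) stop("dose must be > 0", call. = FALSE)
  if (time < 0) stop("time must be >= 0", call. = FALSE)
  structure(list(compound = compound, dose = dose, time = time,
                 formulation = formulation,
                 prandial_state = prandial_state),
            class = "dose_event")
}

#' Build a repeated-dose regimen
#'
#' @param compound Compound name.
#' @param dose Dose per administration, mg.
#' @param n_doses Number of administrations.
#' @param interval Dosing interval, h.
#' @param start Time of the first dose, h.
#' @param formulation A [formulation()].
#' @param prandial_state Prandial state applied to every dose.
#' @return A list of [dose_event()]s.
#' @export
regimen <- function(compound, dose, n_doses = 1, interval = 24, start = 0,
                    formulation = ketopbpk::formulation("solution"),
                    prandial_state = "fasted") {
  lapply(seq_len(n_doses) - 1, function(i)
    dose_event(compound, dose, start + i * interval, formulation,
               prandial_state))
}

#' Resolve an unknown prandial state
#'
#' Applies the fed-state assumption rules used when a study protocol does
#' not state the prandial condition: the fed state is assumed if (i) the
#' observed time of maximum concentration is delayed beyond two hours,
#' (ii) multiple doses are administered within a day (a continuous fasted
#' state being unlikely), or (iii) single oral tablet doses of 800 mg or
#' more are given.  A declared state is returned unchanged.
#'
#' @param observed_tmax Observed T_max in hours, or `NA`/`NULL` if unknown.
#' @param doses_per_day Number of administrations per day.
#' @param single_dose Dose per administration, mg.
#' @param declared `"fasted"`, `"fed"` or `"unknown"`.
#' @return `"fasted"` or `"fed"`.
#' @examples
#' resolve_prandial_state(4, 1, 200, "unknown")     # "fed" (rule i)
#' resolve_prandial_state(NA, 2, 200, "unknown")    # "fed" (rule ii)
#' resolve_prandial_state(1.5, 1, 200, "unknown")   # "fasted"
#' @export
resolve_prandial_state <- function(observed_tmax = NA, doses_per_day = 1,
                                   single_dose = NA,
                                   declared = c("unknown", "fasted", "fed")) {
  declared <- match.arg(declared)
  if (declared != "unknown") return(declared)
  rule_i <- !is.null(observed_tmax) && !is.na(observed_tmax) &&
    observed_tmax > 2
  rule_ii <- doses_per_day > 1
  rule_iii <- !is.na(single_dose) && single_dose >= 800
  if (rule_i || rule_ii || rule_iii) "fed" else "fasted"
}

# Aqueous diffusion coefficient used in dissolution, cm^2/min.
.DIFFUSION_COEF <- 3e-4
# Diffusion layer cap, cm (30 um).
.DIFFUSION_LAYER_MAX <- 30e-4

#' Particle dissolution rate
#'
#' Noyes--Whitney dissolution of one particle-size bin: the flux is
#' proportional to the remaining solid surface area (taken as the specific
#' surface of particles at the bin's nominal radius, `3 m / (rho r0)`) and
#' to the solubility gap `S - C`.  Supersaturation never precipitates:
#' negative gaps give a rate of zero.
#'
#' @param solid_mass Remaining undissolved mass in the bin, umol.
#' @param radius Nominal bin particle radius, um.
#' @param local_solubility Solubility at the segment pH, umol/L.
#' @param dissolved_conc Current dissolved concentration, umol/L.
#' @param MW Molecular weight, g/mol (converts concentrations to mass).
#' @param density Particle density, g/cm^3.
#' @return Dissolution rate, umol/min (>= 0).
#' @export
dissolution_rate <- function(solid_mass, radius, local_solubility,
                             dissolved_conc, MW, density = 1.2) {
  r0 <- radius * 1e-4                      # um -> cm
  h <- pmin(r0, .DIFFUSION_LAYER_MAX)
  gap <- pmax(local_solubility - dissolved_conc, 0)  # umol/L
  # specific dissolution coefficient 3 D / (rho r0 h), converted so that
  # umol quantities and umol/L concentrations can be used directly
  k <- 3 * .DIFFUSION_COEF * MW / (density * 1e3 * r0 * h * 1e6)
  pmax(solid_mass, 0) * k * gap
}
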