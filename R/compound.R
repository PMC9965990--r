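# Compound parameter container and the distribution inputs computed from it:
# ionization, pH-dependent solubility, tissue partitioning and cellular
# permeability.

#' Create a compound parameter set
#'
#' Container for all drug-dependent parameters of one compound: molecular
#' weight, acid/base pKa values, tabulated aqueous solubility, lipophilicity,
#' plasma protein binding, permeabilities, excretion fractions, the kinetic
#' processes the compound undergoes (Michaelis--Menten metabolism, active
#' efflux, enzyme-normalized first-order clearance) and the proteins it
#' inhibits competitively.
#'
#' @param name Compound identifier.
#' @param MW Molecular weight, g/mol.
#' @param pKa Data frame or list with columns/fields `value` and `type`
#'   (`"acid"` or `"base"`); may be empty for neutral compounds.
#' @param solubility Data frame or list with fields `pH` and `mg_per_L`
#'   (strictly positive); at least one point.
#' @param logP Log octanol--water partition coefficient.
#' @param fu Fraction unbound in plasma, in (0, 1].
#' @param blood_plasma_ratio Whole-blood to plasma concentration ratio
#'   (default 1); for drugs bound to plasma proteins with little
#'   erythrocyte association this is below 1 and plasma concentrations
#'   exceed blood concentrations.
#' @param partition_method `"Berezhkovskiy"`, `"RodgersRowland"` or
#'   `"SchmittChargeDependent"`.
#' @param permeability_method `"PKSimStandard"` or
#'   `"SchmittChargeDependent"`.
#' @param intestinal_permeability Named numeric with entries `fasted` and
#'   `fed`, cm/min (may be `NULL` for compounds never dosed orally).
#' @param GFR_fraction Fraction of glomerularly filtered drug appearing in
#'   urine.
#' @param EHC_continuous_fraction Fraction of biliary drug continuously
#'   released into the duodenum (the remainder is routed to feces).
#' @param plasma_restricted If `TRUE` the compound cannot permeate between
#'   cells and plasma anywhere in the body (used for M2, which was never
#'   observed in plasma).
#' @param processes List of kinetic processes; each a list with fields
#'   `protein`, `kind` (`"MichaelisMenten"`, `"ActiveEffluxMM"` or
#'   `"FirstOrderEnzymeNormalized"`), `K_M` (umol/L) and `k_cat` (1/min) for
#'   saturable kinds or `CL_spec` (L/umol/min) for first-order, and
#'   `product` (a compound name or `"sink"`).
#' @param inhibitions List of competitive reversible inhibition entries, each
#'   with `target_protein` (`"CYP3A4"` or `"P-gp"`) and `K_i` (umol/L).
#' @param metadata Optional named list of literature values kept for
#'   reference only (not used in computation).
#' @return An object of class `compound`.
#' @export
compound <- function(name, MW, pKa = NULL, solubility, logP, fu,
                     blood_plasma_ratio = 1,
                     partition_method = c("Berezhkovskiy", "RodgersRowland",
                                          "SchmittChargeDependent"),
                     permeability_method = c("PKSimStandard",
                                             "SchmittChargeDependent"),
                     intestinal_permeability = NULL,
                     GFR_fraction = 1,
                     EHC_continuous_fraction = 1,
                     plasma_restricted = FALSE,
                     processes = list(),
                     inhibitions = list(),
                     metadata = list()) {
  partition_method <- match.arg(partition_method)
  permeability_method <- match.arg(permeability_method)
  pKa <- .as_pka(pKa)
  solubility <- .as_solubility(solubility)
  if (!is.numeric(MW) || MW <= 0) stop("MW must be positive", call. = FALSE)
  if (!is.numeric(fu) || fu <= 0 || fu > 1)
    stop("fu must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(blood_plasma_ratio) || blood_plasma_ratio <= 0)
    stop("blood_plasma_ratio must be positive", call. = FALSE)
  processes <- lapply(processes, .validate_process)
  inhibitions <- lapply(inhibitions, .validate_inhibition)
  structure(list(
    name = name, MW = MW, pKa = pKa, solubility = solubility, logP = logP,
    fu = fu, blood_plasma_ratio = blood_plasma_ratio,
    partition_method = partition_method,
    permeability_method = permeability_method,
    intestinal_permeability = intestinal_permeability,
    GFR_fraction = GFR_fraction,
    EHC_continuous_fraction = EHC_continuous_fraction,
    plasma_restricted = isTRUE(plasma_restricted),
    processes = processes, inhibitions = inhibitions,
    metadata = metadata
  ), class = "compound")
}

.as_pka <- function(pKa) {
  if (is.null(pKa) || (is.data.frame(pKa) && nrow(pKa) == 0) ||
      length(pKa) == 0)
    return(data.frame(value = numeric(0), type = character(0),
                      stringsAsFactors = FALSE))
  if (!is.data.frame(pKa))
    pKa <- do.call(rbind, lapply(pKa, function(p)
      data.frame(value = p$value, type = p$type, stringsAsFactors = FALSE)))
  stopifnot(all(pKa$type %in% c("acid", "base")))
  pKa
}

.as_solubility <- function(s) {
  if (!is.data.frame(s))
    s <- do.call(rbind, lapply(s, function(p)
      data.frame(pH = p$pH, mg_per_L = p$mg_per_L, stringsAsFactors = FALSE)))
  if (nrow(s) == 0) stop("solubility table must be non-empty", call. = FALSE)
  if (any(s$mg_per_L <= 0))
    stop("solubilities must be strictly positive", call. = FALSE)
  s[order(s$pH), , drop = FALSE]
}

.validate_process <- function(p) {
  stopifnot(!is.null(p$protein), !is.null(p$kind))
  if (!p$kind %in% c("MichaelisMenten", "ActiveEffluxMM",
                     "FirstOrderEnzymeNormalized"))
    stop("unknown process kind: ", p$kind, call. = FALSE)
  if (p$kind %in% c("MichaelisMenten", "ActiveEffluxMM")) {
    if (is.null(p$K_M) || p$K_M <= 0) stop("K_M must be > 0", call. = FALSE)
    if (is.null(p$k_cat) || p$k_cat < 0)
      stop("k_cat must be >= 0", call. = FALSE)
    if (!is.null(p$CL_spec))
      stop("saturable processes take K_M/k_cat, not CL_spec", call. = FALSE)
  } else {
    if (is.null(p$CL_spec) || p$CL_spec < 0)
      stop("CL_spec must be >= 0", call. = FALSE)
    if (!is.null(p$K_M) || !is.null(p$k_cat))
      stop("first-order processes take CL_spec only", call. = FALSE)
  }
  if (is.null(p$product)) p$product <- "sink"
  p
}

.validate_inhibition <- function(i) {
  stopifnot(!is.null(i$target_protein), !is.null(i$K_i))
  if (!i$target_protein %in% c("CYP3A4", "P-gp"))
    stop("inhibition targets are restricted to CYP3A4 and P-gp",
         call. = FALSE)
  if (i$K_i <= 0) stop("K_i must be > 0", call. = FALSE)
  i$mechanism <- "competitive reversible"
  i
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s  MW %.2f g/mol, logP %.2f, fu %.3f\n",
              x$name, x$MW, x$logP, x$fu))
  cat(sprintf("  partition: %s | cellular permeability: %s%s\n",
              x$partition_method, x$permeability_method,
              if (x$plasma_restricted) " | plasma-restricted" else ""))
  for (p in x$processes)
    cat(sprintf("  process %s (%s) -> %s\n", p$protein, p$kind, p$product))
  for (i in x$inhibitions)
    cat(sprintf("  inhibits %s, K_i %g umol/L\n", i$target_protein, i$K_i))
  invisible(x)
}

#' Ionized fractions by Henderson--Hasselbalch
#'
#' Computes the neutral, cationic and anionic fractions of a compound at a
#' given pH, treating all pKa sites as independent.  A molecule counts as
#' cationic if any basic site is protonated, and as anionic if some acidic
#' site is deprotonated while no basic site is protonated (zwitterions are
#' lumped with the cations).
#'
#' @param compound A [compound()] object.
#' @param pH pH value in \[0, 14\].
#' @return Named numeric vector `c(neutral, cationic, anionic)` summing to 1.
#' @examples
#' ktz <- load_compound("ketoconazole")
#' ionized_fractions(ktz, 7.4)
#' @export
ionized_fractions <- function(compound, pH) {
  stopifnot(inherits(compound, "compound"))
  if (!is.numeric(pH) || pH < 0 || pH > 14)
    stop("pH must lie in [0, 14]", call. = FALSE)
  pka <- compound$pKa
  bases <- pka$value[pka$type == "base"]
  acids <- pka$value[pka$type == "acid"]
  # probability every basic site is unprotonated / every acidic site neutral
  p_base_neutral <- prod(1 / (1 + 10^(bases - pH)))
  p_acid_neutral <- prod(1 / (1 + 10^(pH - acids)))
  p_b <- 1 - p_base_neutral   # any basic site protonated
  p_a <- 1 - p_acid_neutral   # any acidic site deprotonated
  c(neutral = (1 - p_b) * (1 - p_a),
    cationic = p_b,
    anionic = p_a * (1 - p_b))
}

#' Aqueous solubility at a given pH
#'
#' Interpolates the tabulated solubility points log10-linearly in pH and
#' extrapolates as a constant beyond the table, so the returned value is
#' always positive and exact at tabulated pH values.
#'
#' @param compound A [compound()] object.
#' @param pH pH value.
#' @return Solubility in mg/L.
#' @examples
#' ktz <- load_compound("ketoconazole")
#' solubility_at_ph(ktz, 7)    # tabulated: 5.40 mg/L
#' solubility_at_ph(ktz, 7.25) # log-linear between 5.40 and 6.00
#' @export
solubility_at_ph <- function(compound, pH) {
  stopifnot(inherits(compound, "compound"))
  tab <- compound$solubility
  if (nrow(tab) == 1) return(tab$mg_per_L[1])
  if (pH <= tab$pH[1]) return(tab$mg_per_L[1])
  n <- nrow(tab)
  if (pH >= tab$pH[n]) return(tab$mg_per_L[n])
  10^stats::approx(tab$pH, log10(tab$mg_per_L), xout = pH)$y
}

# Poulin-style fraction unbound in tissue: interstitial/tissue binding
# proteins assumed present at half the plasma binding capacity.
.fu_tissue <- function(fu) 1 / (1 + 0.5 * (1 - fu) / fu)

.lipid_partition <- function(P, f_nl, f_ph, f_w) {
  P * (f_nl + 0.3 * f_ph) + (f_w + 0.7 * f_ph)
}

#' Tissue-to-plasma partition coefficient
#'
#' Computes the cell-to-plasma partition coefficient of a compound in an
#' organ from the organ's composition (water, neutral lipid, phospholipid)
#' using one of three published composition-based methods.  The
#' Berezhkovskiy method partitions the neutral species between tissue lipid
#' and water with a tissue-binding correction; the Rodgers--Rowland method
#' additionally accounts for intracellular ionization at cytosolic pH; the
#' charge-dependent Schmitt method weights the membrane affinity of each
#' ionization species separately (cations retain full phospholipid affinity
#' through electrostatic attraction to acidic head groups, anions are
#' repelled).
#'
#' @param compound A [compound()] object.
#' @param organ A single-row slice of `individual$organs`, or an organ name
#'   together with `individual`.
#' @param method Partition method; defaults to the compound's declared
#'   method.
#' @param individual Optional `individual` used to resolve `organ` by name.
#' @return Positive unitless cell-to-plasma partition coefficient.
#' @export
partition_coefficient <- function(compound, organ, method = NULL,
                                  individual = NULL) {
  stopifnot(inherits(compound, "compound"))
  if (is.character(organ)) {
    if (is.null(individual))
      stop("supply 'individual' when passing an organ name", call. = FALSE)
    organ <- individual$organs[individual$organs$name == organ, , drop = FALSE]
  }
  if (nrow(organ) != 1 || any(is.na(organ$f_water)))
    stop("organ composition missing", call. = FALSE)
  if (is.null(method)) method <- compound$partition_method
  P <- 10^compound$logP
  fu <- compound$fu
  fr_pl <- ionized_fractions(compound, 7.4)
  plasma_term <- .lipid_partition(P, 0.0035, 0.00225, 0.945)

  kp <- switch(method,
    Berezhkovskiy = {
      # adipose partitions the neutral species only (logD); elsewhere a
      # tissue-binding correction applies
      Pt <- if (organ$name == "adipose") P * fr_pl[["neutral"]] else P
      tissue_term <- .lipid_partition(Pt, organ$f_neutral_lipid,
                                      organ$f_phospholipid, organ$f_water)
      fut <- if (organ$name == "adipose") 1 else .fu_tissue(fu)
      (tissue_term / plasma_term) * fu / fut
    },
    RodgersRowland = {
      pka_b <- compound$pKa$value[compound$pKa$type == "base"]
      pka_eff <- if (length(pka_b)) max(pka_b) else -Inf
      ph_iw <- organ$intracellular_pH
      ion_iw <- 1 + 10^(pka_eff - ph_iw)
      ion_p <- 1 + 10^(pka_eff - 7.4)
      f_iw <- 0.65 * organ$f_water
      f_ew <- 0.35 * organ$f_water
      kpu <- f_ew + (ion_iw / ion_p) * f_iw +
        (P * organ$f_neutral_lipid +
           (0.3 * P + 0.7) * organ$f_phospholipid) / ion_p
      kpu * fu
    },
    SchmittChargeDependent = {
      fr_t <- ionized_fractions(compound, organ$intracellular_pH)
      # species-weighted membrane affinity: neutral 1, cation 1 (reduced
      # lipophilicity offset by electrostatic attraction to acidic
      # phospholipid head groups), anion strongly repelled; partitioning
      # is phospholipid-membrane-centric, with neutral storage lipid
      # contributing at reduced weight
      w <- c(neutral = 1, cationic = 1, anionic = 0.05)
      P_eff <- P * sum(fr_t * w[names(fr_t)])
      tissue_term <- P_eff * (organ$f_phospholipid +
                                0.3 * organ$f_neutral_lipid) +
        organ$f_water
      plasma_mem <- P * (0.00225 + 0.3 * 0.0035) + 0.945
      (tissue_term / plasma_mem) * fu / .fu_tissue(fu)
    },
    stop("unknown partition method: ", method, call. = FALSE)
  )
  unname(max(kp, 1e-6))
}

# Baseline lipophilicity/size permeability relation shared by both methods,
# cm/min.  The flux it drives acts on unbound aqueous concentrations, so
# the scale is set such that, together with the embedded exchange areas,
# moderately lipophilic drugs (logP 2-3, MW ~500) traverse cells with
# unbound equilibration half-times of minutes (e.g. enterocyte transit
# during absorption), as transcellular passive diffusion requires.
.permeability_standard <- function(logP, MW) {
  1.2e-2 * 10^logP / sqrt(MW)
}

#' Cellular membrane permeability
#'
#' Permeability of a compound across cell membranes (cm/min), computed from
#' lipophilicity and molecular size.  The standard relation increases with
#' logP and decreases with molecular weight; the charge-dependent Schmitt
#' variant additionally scales by the neutral fraction at plasma pH, which
#' penalizes compounds ionized at physiological pH.
#'
#' @param compound A [compound()] object.
#' @param method Permeability method; defaults to the compound's declared
#'   method.
#' @return Permeability in cm/min.
#' @export
cellular_permeability <- function(compound, method = NULL) {
  stopifnot(inherits(compound, "compound"))
  if (is.null(method)) method <- compound$permeability_method
  base <- .permeability_standard(compound$logP, compound$MW)
  switch(method,
    PKSimStandard = base,
    SchmittChargeDependent =
      base * ionized_fractions(compound, 7.4)[["neutral"]],
    stop("unknown permeability method: ", method, call. = FALSE)
  )
}

#' Load a shipped compound parameter set
#'
#' Reads one of the compound parameter files shipped with the package
#' (`ketoconazole`, `m1`, `m2` and the victim-drug fixtures) or an arbitrary
#' YAML file following the same schema.
#'
#' @param name Compound name (file base name under
#'   `inst/extdata/compounds`) or a path to a YAML file.
#' @return A [compound()] object.
#' @examples
#' ktz <- load_compound("ketoconazole")
#' ktz$processes[[1]]$K_M
#' @export
load_compound <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "compounds", paste0(name, ".yaml"),
                package = "ketopbpk")
  if (!nzchar(path) || !file.exists(path))
    stop("no compound file for '", name, "'", call. = FALSE)
  x <- yaml::read_yaml(path)
  .compound_from_list(x)
}

.compound_from_list <- function(x) {
  ip <- x$intestinal_permeability
  if (!is.null(ip)) ip <- unlist(ip)
  cmp <- compound(
    name = x$name, MW = x$MW, pKa = x$pKa,
    solubility = x$solubility, logP = x$logP, fu = x$fu,
    blood_plasma_ratio =
      if (is.null(x$blood_plasma_ratio)) 1 else x$blood_plasma_ratio,
    partition_method = x$partition_method,
    permeability_method = x$permeability_method,
    intestinal_permeability = ip,
    GFR_fraction = if (is.null(x$GFR_fraction)) 1 else x$GFR_fraction,
    EHC_continuous_fraction =
      if (is.null(x$EHC_continuous_fraction)) 1 else x$EHC_continuous_fraction,
    plasma_restricted = isTRUE(x$plasma_restricted),
    processes = if (is.null(x$processes)) list() else x$processes,
    inhibitions = if (is.null(x$inhibitions)) list() else x$inhibitions,
    metadata = if (is.null(x$metadata)) list() else x$metadata
  )
  .assert_surrogacy(cmp)
  cmp
}

# For ketoconazole the CYP3A4 and P-gp K_M values are surrogated by the
# corresponding autoinhibition K_i values; assert the coupling at load time.
.assert_surrogacy <- function(cmp) {
  if (cmp$name != "ketoconazole") return(invisible(cmp))
  ki <- vapply(cmp$inhibitions, function(i) i$K_i, numeric(1))
  names(ki) <- vapply(cmp$inhibitions, function(i) i$target_protein,
                      character(1))
  for (p in cmp$processes) {
    if (p$protein == "CYP3A4" && p$kind == "MichaelisMenten" &&
        !isTRUE(all.equal(p$K_M, ki[["CYP3A4"]])))
      stop("ketoconazole CYP3A4 K_M must equal its CYP3A4 K_i (surrogacy)",
           call. = FALSE)
    if (p$protein == "P-gp" && p$kind == "ActiveEffluxMM" &&
        !isTRUE(all.equal(p$K_M, ki[["P-gp"]])))
      stop("ketoconazole P-gp K_M must equal its P-gp K_i (surrogacy)",
           call. = FALSE)
  }
  invisible(cmp)
}
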