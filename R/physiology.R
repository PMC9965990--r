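# Reference physiology: organ volumes, blood flows, tissue composition and
# enzyme/transporter pools for a standard European adult.
#
# Values are literature-informed (ICRP-style reference anatomy and standard
# tissue-composition tables used by perfusion/permeability PBPK methods).
# Volumes in L, flows in L/min (arterial inflow; the liver additionally
# receives portal blood from gut wall and spleen), organ density 1 kg/L.

.REFERENCE_BODY_WEIGHT <- 73   # kg
.REFERENCE_HEIGHT      <- 176  # cm
.REFERENCE_AGE         <- 30   # years
.REFERENCE_GFR         <- 120  # mL/min
.REFERENCE_HEMATOCRIT  <- 0.45

.TISSUE_ORGANS <- c("lung", "liver", "kidney", "gut wall", "adipose",
                    "muscle", "skin", "bone", "brain", "heart", "spleen",
                    "rest")
.ALL_ORGANS <- c("venous blood", "arterial blood", .TISSUE_ORGANS)

# volume L; blood_flow L/min = arterial inflow (lung carries cardiac output,
# set at build time); sub-fractions of organ volume (plasma, interstitial,
# intracellular; remainder erythrocytes); composition fractions (water,
# neutral lipid, phospholipid, protein); intracellular pH.
.ORGAN_TABLE <- data.frame(
  name  = .ALL_ORGANS,
  volume = c(3.70, 1.60, 0.50, 1.80, 0.31, 1.10, 14.50, 29.00, 3.30, 10.50,
             1.45, 0.33, 0.15, 2.00),
  blood_flow = c(NA, NA, NA, 0.30, 1.10, 1.00, 0.32, 1.05, 0.30, 0.32,
                 0.70, 0.24, 0.15, 0.33),
  f_plasma       = c(0.55, 0.55, 0.11, 0.10, 0.10, 0.03, 0.02, 0.03, 0.02,
                     0.03, 0.03, 0.06, 0.20, 0.04),
  f_interstitial = c(0.00, 0.00, 0.19, 0.16, 0.20, 0.28, 0.14, 0.12, 0.35,
                     0.10, 0.17, 0.14, 0.15, 0.15),
  f_intracellular = c(0.00, 0.00, 0.66, 0.70, 0.66, 0.67, 0.82, 0.84, 0.60,
                      0.85, 0.79, 0.78, 0.62, 0.80),
  f_water = c(0.945, 0.945, 0.811, 0.745, 0.783, 0.718, 0.180, 0.760, 0.718,
              0.439, 0.770, 0.758, 0.788, 0.760),
  f_neutral_lipid = c(0.0035, 0.0035, 0.0030, 0.0348, 0.0207, 0.0487, 0.790,
                      0.0220, 0.0284, 0.0740, 0.0510, 0.0115, 0.0201, 0.0400),
  f_phospholipid = c(0.00225, 0.00225, 0.0090, 0.0252, 0.0162, 0.0163, 0.0020,
                     0.0072, 0.0111, 0.0011, 0.0565, 0.0166, 0.0198, 0.0100),
  f_protein = c(0.060, 0.060, 0.130, 0.200, 0.160, 0.150, 0.020, 0.190,
                0.230, 0.200, 0.110, 0.170, 0.180, 0.150),
  intracellular_pH = c(7.4, 7.4, 7.0, 7.0, 7.0, 7.0, 7.0, 7.0, 7.0, 7.0,
                       7.0, 7.0, 7.0, 7.0),
  stringsAsFactors = FALSE
)

# Effective membrane exchange area between the lumped extracellular space and
# the intracellular space, cm^2 per L organ volume.  A single effective value
# is used for all organs; together with compound cellular permeability it
# sets the permeability-limited equilibration time of the cellular space.
.CELL_EXCHANGE_AREA_PER_L <- 1e5

# Enzyme/transporter tissue distribution (micromol protein per L of
# intracellular organ water for enzymes; membrane-associated for P-gp).
# Localization: AADAC/UGT1A4/FMO3 liver only; CYP3A4 liver + gut wall;
# P-gp apical gut wall, liver canalicular membrane, kidney.
.PROTEIN_TABLE <- data.frame(
  protein = c("CYP3A4", "CYP3A4", "AADAC", "UGT1A4", "FMO3",
              "P-gp", "P-gp", "P-gp"),
  organ   = c("liver", "gut wall", "liver", "liver", "liver",
              "gut wall", "liver", "kidney"),
  concentration = c(4.32, 0.40, 1.00, 1.00, 1.00,
                    0.10, 0.10, 0.06),
  stringsAsFactors = FALSE
)

.KNOWN_PROTEINS <- c("CYP3A4", "AADAC", "UGT1A4", "FMO3", "P-gp")

#' Build a reference virtual individual
#'
#' Constructs the whole-body physiology (organ volumes, blood flows, tissue
#' composition, enzyme and transporter pools, glomerular filtration rate) on
#' which all simulations run.  The embedded tables describe a standard
#' European adult; organ volumes, blood flows and GFR scale linearly with
#' body weight relative to the 73 kg reference.
#'
#' @param age Age in years (18--90).
#' @param body_weight Body weight in kg, or `NULL` to use the embedded
#'   reference value (73 kg).
#' @param height Height in cm, or `NULL` for the reference value (176 cm).
#' @param sex `"male"` or `"female"` (stored; the embedded reference tables
#'   are sex-independent).
#' @return An object of class `individual`: a list with demographics, `gfr`
#'   (mL/min), an `organs` data frame and a `pools` data frame of protein
#'   concentrations.
#' @examples
#' ind <- build_reference_individual()
#' sum(ind$organs$volume)  # approximately body weight at density 1 kg/L
#' @export
build_reference_individual <- function(age = .REFERENCE_AGE,
                                       body_weight = NULL,
                                       height = NULL,
                                       sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (!is.numeric(age) || length(age) != 1 || is.na(age) ||
      age < 18 || age > 90)
    stop("'age' must be a single value in [18, 90]", call. = FALSE)
  if (is.null(body_weight)) body_weight <- .REFERENCE_BODY_WEIGHT
  if (is.null(height)) height <- .REFERENCE_HEIGHT
  if (!is.numeric(body_weight) || body_weight <= 0)
    stop("'body_weight' must be positive", call. = FALSE)
  if (!is.numeric(height) || height <= 0)
    stop("'height' must be positive", call. = FALSE)

  scale <- body_weight / .REFERENCE_BODY_WEIGHT
  organs <- .ORGAN_TABLE
  organs$volume <- organs$volume * scale
  organs$blood_flow <- organs$blood_flow * scale
  co <- sum(organs$blood_flow[!is.na(organs$blood_flow)])
  organs$blood_flow[organs$name == "lung"] <- co

  ind <- structure(list(
    age = age, sex = sex, body_weight = body_weight, height = height,
    hematocrit = .REFERENCE_HEMATOCRIT,
    gfr = .REFERENCE_GFR * scale,
    cardiac_output = co,
    cell_exchange_area_per_L = .CELL_EXCHANGE_AREA_PER_L,
    organs = organs,
    pools = .PROTEIN_TABLE
  ), class = "individual")
  validate_individual(ind)
  ind
}

#' Validate an individual
#'
#' Checks the structural invariants of a virtual individual: strictly
#' positive volumes, flows and GFR, composition fractions in \[0, 1\] with
#' sub-fraction sums at most 1, presence of the core organs, and total organ
#' volume within 15% of body weight at density 1 kg/L.
#'
#' @param ind An `individual` object.
#' @return `ind`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_individual <- function(ind) {
  stopifnot(inherits(ind, "individual"))
  org <- ind$organs
  core <- c("venous blood", "arterial blood", "lung", "liver", "kidney",
            "gut wall")
  if (!all(core %in% org$name))
    stop("individual lacks core organs: ",
         paste(setdiff(core, org$name), collapse = ", "), call. = FALSE)
  if (any(org$volume <= 0))
    stop("organ volumes must be strictly positive", call. = FALSE)
  flows <- org$blood_flow[!is.na(org$blood_flow)]
  if (any(flows <= 0))
    stop("organ blood flows must be strictly positive", call. = FALSE)
  if (!is.numeric(ind$gfr) || ind$gfr <= 0)
    stop("GFR must be positive", call. = FALSE)
  comp <- as.matrix(org[, c("f_plasma", "f_interstitial", "f_intracellular",
                            "f_water", "f_neutral_lipid", "f_phospholipid",
                            "f_protein")])
  if (any(comp < 0 | comp > 1))
    stop("composition fractions must lie in [0, 1]", call. = FALSE)
  subsum <- org$f_plasma + org$f_interstitial + org$f_intracellular
  if (any(subsum > 1 + 1e-9))
    stop("sub-compartment fractions must sum to at most 1", call. = FALSE)
  vol_ratio <- sum(org$volume) / ind$body_weight
  if (abs(vol_ratio - 1) > 0.15)
    stop("sum of organ volumes deviates from body weight by more than 15%",
         call. = FALSE)
  invisible(ind)
}

#' Amount of an enzyme or transporter in an organ
#'
#' Returns the protein amount as pool concentration times the organ's
#' intracellular volume.  Proteins not expressed in the queried organ return
#' zero, so the amount is linear in organ volume.
#'
#' @param ind An `individual`.
#' @param protein One of `"CYP3A4"`, `"AADAC"`, `"UGT1A4"`, `"FMO3"`,
#'   `"P-gp"`.
#' @param organ Organ name present in `ind$organs`.
#' @return Protein amount in micromol.
#' @examples
#' ind <- build_reference_individual()
#' protein_amount(ind, "CYP3A4", "liver")
#' protein_amount(ind, "FMO3", "muscle")  # 0: FMO3 is hepatic
#' @export
protein_amount <- function(ind, protein, organ) {
  stopifnot(inherits(ind, "individual"))
  if (!protein %in% .KNOWN_PROTEINS)
    stop("unknown protein: ", protein, call. = FALSE)
  row <- ind$organs[ind$organs$name == organ, , drop = FALSE]
  if (nrow(row) == 0)
    stop("organ not present in individual: ", organ, call. = FALSE)
  pool <- ind$pools[ind$pools$protein == protein & ind$pools$organ == organ, ]
  if (nrow(pool) == 0) return(0)
  v_ic <- row$volume * row$f_intracellular
  sum(pool$concentration) * v_ic
}

#' @export
print.individual <- function(x, ...) {
  cat(sprintf("<individual> %s, %g y, %g kg, %g cm\n",
              x$sex, x$age, x$body_weight, x$height))
  cat(sprintf("  cardiac output %.2f L/min, GFR %.0f mL/min, %d organs\n",
              x$cardiac_output, x$gfr, nrow(x$organs)))
  invisible(x)
}

#' Serialize an individual to a plain list
#'
#' Produces a nested list (suitable for YAML/JSON export) that
#' [individual_from_list()] restores losslessly.
#'
#' @param ind An `individual`.
#' @return A named list.
#' @export
individual_to_list <- function(ind) {
  stopifnot(inherits(ind, "individual"))
  list(
    demographics = list(age = ind$age, sex = ind$sex,
                        body_weight = ind$body_weight, height = ind$height,
                        hematocrit = ind$hematocrit),
    gfr = ind$gfr,
    cardiac_output = ind$cardiac_output,
    cell_exchange_area_per_L = ind$cell_exchange_area_per_L,
    organs = lapply(seq_len(nrow(ind$organs)), function(i)
      as.list(ind$organs[i, , drop = FALSE])),
    pools = lapply(seq_len(nrow(ind$pools)), function(i)
      as.list(ind$pools[i, , drop = FALSE]))
  )
}

#' Restore an individual from a plain list
#'
#' Inverse of [individual_to_list()].
#'
#' @param x A list produced by [individual_to_list()] (possibly after a
#'   YAML/JSON round trip).
#' @return An `individual`.
#' @export
individual_from_list <- function(x) {
  organs <- do.call(rbind, lapply(x$organs, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  pools <- do.call(rbind, lapply(x$pools, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(organs) <- NULL
  rownames(pools) <- NULL
  ind <- structure(list(
    age = x$demographics$age, sex = x$demographics$sex,
    body_weight = x$demographics$body_weight,
    height = x$demographics$height,
    hematocrit = x$demographics$hematocrit,
    gfr = x$gfr, cardiac_output = x$cardiac_output,
    cell_exchange_area_per_L = x$cell_exchange_area_per_L,
    organs = organs, pools = pools
  ), class = "individual")
  validate_individual(ind)
  ind
}

#' Write an individual to a YAML or JSON file
#'
#' @param ind An `individual`.
#' @param path Output path; format chosen from the extension (`.yaml`,
#'   `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_individual <- function(ind, path) {
  x <- individual_to_list(ind)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Read an individual from a YAML or JSON file
#'
#' @param path File written by [write_individual()].
#' @return An `individual`.
#' @export
read_individual <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  individual_from_list(x)
}
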