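# Elementary kinetic rate laws: competitive inhibition, Michaelis-Menten
# metabolism/transport and enzyme-normalized first-order clearance.

#' Apparent Michaelis constant under competitive reversible inhibition
#'
#' `K_M * (1 + sum_j I_j / K_i_j)` for a set of competitive inhibitors at
#' unbound local concentrations `I_j`.  With no inhibitors the Michaelis
#' constant is returned unchanged.
#'
#' @param K_M Michaelis constant, umol/L.
#' @param inhibitors List of `c(conc, K_i)` pairs (umol/L each), or a
#'   two-column matrix; may be empty.
#' @return Apparent K_M, umol/L.
#' @examples
#' apparent_km(0.008, list())                      # 0.008
#' apparent_km(0.008, list(c(0.008, 0.008)))       # 0.016
#' @export
apparent_km <- function(K_M, inhibitors = list()) {
  if (length(inhibitors) == 0) return(K_M)
  if (is.matrix(inhibitors)) {
    ratio <- sum(inhibitors[, 1] / inhibitors[, 2])
  } else {
    ratio <- sum(vapply(inhibitors, function(p) p[1] / p[2], numeric(1)))
  }
  K_M * (1 + ratio)
}

#' Michaelis--Menten rate
#'
#' `v = k_cat * E * C / (K_M_app + C)`, with `V_max = k_cat * E`.
#'
#' @param C_unbound Unbound substrate concentration, umol/L.
#' @param K_M_app (Apparent) Michaelis constant, umol/L.
#' @param protein_amount Enzyme or transporter amount, umol.
#' @param k_cat Catalytic rate constant, 1/min.
#' @return Rate in umol/min.
#' @export
mm_rate <- function(C_unbound, K_M_app, protein_amount, k_cat) {
  k_cat * protein_amount * C_unbound / (K_M_app + C_unbound)
}

#' Enzyme-normalized first-order rate
#'
#' `v = CL_spec * [E] * C * V`: a linear clearance proportional to the local
#' enzyme concentration, used where no saturable in vitro data exist (the
#' FMO3-mediated elimination of M2).
#'
#' @param C_unbound Unbound substrate concentration, umol/L.
#' @param CL_spec Specific clearance, L/umol/min.
#' @param protein_conc Enzyme concentration, umol/L.
#' @param volume Compartment volume, L.
#' @return Rate in umol/min.
#' @export
first_order_enzyme_rate <- function(C_unbound, CL_spec, protein_conc,
                                    volume) {
  CL_spec * protein_conc * C_unbound * volume
}
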