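# Whole-body model assembly: translates an individual, a set of compounds,
# an interaction scenario and a dosing regimen into the coupled ODE system
# (distribution, GI transit/dissolution/absorption, metabolism with
# competitive inhibition, efflux, biliary and renal excretion).
#
# Internal units: micromol for amounts, minutes for time, L and L/min for
# volumes and flows, umol/L for concentrations.

.SCENARIOS <- c("P", "P_M1", "P_M1_M2", "none")
.BILE_RELEASE_RATE <- 0.03  # 1/min, continuous release into the duodenum

#' Interaction scenario definitions
#'
#' Returns the perpetrator compounds whose competitive inhibition entries
#' are active under a drug--drug interaction scenario: the parent alone
#' (`"P"`), parent plus first metabolite (`"P_M1"`), parent plus both
#' metabolites (`"P_M1_M2"`), or no inhibition at all (`"none"`).
#'
#' @param scenario Scenario label.
#' @return Character vector of active inhibitor compound names.
#' @export
scenario_inhibitors <- function(scenario = .SCENARIOS) {
  scenario <- match.arg(scenario)
  switch(scenario,
         P = "ketoconazole",
         P_M1 = c("ketoconazole", "m1"),
         P_M1_M2 = c("ketoconazole", "m1", "m2"),
         none = character(0))
}

#' Assemble a whole-body PBPK model
#'
#' Builds the coupled ODE system for an arbitrary set of interacting
#' compounds on a virtual individual: perfusion-limited extracellular
#' distribution with permeability-limited cellular spaces, an eight-segment
#' GI tract with particle dissolution and prandial-state-dependent gastric
#' emptying, Michaelis--Menten metabolism with competitive reversible
#' inhibition of CYP3A4 and P-gp evaluated from unbound intracellular
#' inhibitor concentrations, P-gp efflux (gut wall to lumen, liver to bile,
#' kidney to urine), continuous biliary release into the duodenum, and
#' renal glomerular filtration.
#'
#' @param individual An [build_reference_individual()] object.
#' @param compounds List of [compound()] objects (order defines state
#'   layout).  Metabolite products referenced by any kinetic process must be
#'   present.
#' @param doses List of [dose_event()]s.
#' @param scenario Interaction scenario; see [scenario_inhibitors()].
#' @param k_i_override Optional named list
#'   `list(compound = list("CYP3A4" = K_i, ...))` replacing inhibition
#'   constants (used for scenario-equivalence tests).
#' @return An object of class `pbpk_model`.
#' @export
pbpk_model <- function(individual, compounds, doses = list(),
                       scenario = "P_M1_M2", k_i_override = NULL) {
  stopifnot(inherits(individual, "individual"))
  scenario <- match.arg(scenario, .SCENARIOS)
  if (inherits(compounds, "compound")) compounds <- list(compounds)
  names(compounds) <- vapply(compounds, `[[`, character(1), "name")
  ncomp <- length(compounds)

  # ---- organ geometry -----------------------------------------------------
  org_all <- individual$organs
  org <- org_all[match(.TISSUE_ORGANS, org_all$name), , drop = FALSE]
  if (any(is.na(org$volume)))
    stop("individual lacks tissue organs: ",
         paste(.TISSUE_ORGANS[is.na(org$volume)], collapse = ", "),
         call. = FALSE)
  V <- org$volume
  Vec <- V * (org$f_plasma + org$f_interstitial)
  Vic <- V * org$f_intracellular
  Q <- org$blood_flow
  i_lung <- match("lung", org$name); i_liv <- match("liver", org$name)
  i_kid <- match("kidney", org$name); i_gut <- match("gut wall", org$name)
  i_spl <- match("spleen", org$name)
  i_term <- setdiff(seq_along(V), c(i_lung, i_liv, i_gut, i_spl))
  CO <- individual$cardiac_output
  Q[i_lung] <- 0  # lung perfusion carried explicitly by CO
  Qliv_tot <- Q[i_liv] + Q[i_gut] + Q[i_spl]
  Vven <- org_all$volume[org_all$name == "venous blood"]
  Vart <- org_all$volume[org_all$name == "arterial blood"]
  GFR_L <- individual$gfr / 1000
  area_per_L <- individual$cell_exchange_area_per_L

  # ---- GI geometry (fasted / fed variants) --------------------------------
  gi_fa <- default_gi_tract("fasted"); gi_fe <- default_gi_tract("fed")
  seg <- gi_fa$segments
  nseg <- nrow(seg)
  Vlum <- seg$volume
  SAseg <- seg$surface_area
  ktr <- cbind(fasted = log(2) / gi_fa$segments$transit,
               fed = log(2) / gi_fe$segments$transit)
  pH_seg <- cbind(fasted = gi_fa$segments$pH, fed = gi_fe$segments$pH)
  # gut-wall efflux returns to the absorptive small-intestinal segments
  w_efflux <- numeric(nseg)
  si <- 2:6
  w_efflux[si] <- SAseg[si] / sum(SAseg[si])

  # ---- doses --------------------------------------------------------------
  doses <- lapply(doses, function(d) {
    stopifnot(inherits(d, "dose_event"))
    if (!d$compound %in% names(compounds))
      stop("dose for unknown compound: ", d$compound, call. = FALSE)
    d
  })
  dose_comp <- vapply(doses, `[[`, character(1), "compound")
  # prandial schedule: piecewise constant, switching at dose times
  if (length(doses)) {
    dt <- vapply(doses, `[[`, numeric(1), "time") * 60
    ds <- vapply(doses, function(d)
      if (identical(d$prandial_state, "fed")) 2L else 1L, integer(1))
    o <- order(dt)
    pr_t <- dt[o]; pr_s <- ds[o]
  } else {
    pr_t <- numeric(0); pr_s <- integer(0)
  }

  # ---- inhibition network -------------------------------------------------
  active <- intersect(scenario_inhibitors(scenario), names(compounds))
  inh_cyp <- list(); inh_pgp <- list()
  for (nm in active) {
    for (i in compounds[[nm]]$inhibitions) {
      ki <- i$K_i
      if (!is.null(k_i_override[[nm]][[i$target_protein]]))
        ki <- k_i_override[[nm]][[i$target_protein]]
      entry <- list(comp = match(nm, names(compounds)), K_i = ki)
      if (i$target_protein == "CYP3A4") inh_cyp <- c(inh_cyp, list(entry))
      else inh_pgp <- c(inh_pgp, list(entry))
    }
  }

  # ---- per-compound structures and state layout ---------------------------
  pools <- individual$pools
  cs <- vector("list", ncomp)
  n <- 0L
  nm_state <- character(0)
  push <- function(k, labels) {
    ix <- n + seq_len(k); n <<- n + k
    nm_state <<- c(nm_state, labels); ix
  }
  for (ci in seq_len(ncomp)) {
    cmp <- compounds[[ci]]
    st <- list(name = cmp$name, restricted = cmp$plasma_restricted,
               fu = cmp$fu, MW = cmp$MW, BP = cmp$blood_plasma_ratio,
               fu_b = cmp$fu / cmp$blood_plasma_ratio,
               gfr_frac = cmp$GFR_fraction, ehc = cmp$EHC_continuous_fraction)
    st$Kcu <- vapply(seq_along(V), function(o)
      partition_coefficient(cmp, org[o, , drop = FALSE]), numeric(1))
    Pcell <- cellular_permeability(cmp)
    st$PS <- Pcell * area_per_L * V / 1000  # L/min
    # kinetic processes resolved against the individual's protein pools
    procs <- list()
    for (pr in cmp$processes) {
      hosts <- pools[pools$protein == pr$protein, , drop = FALSE]
      if (nrow(hosts) == 0)
        stop("process protein ", pr$protein, " of compound ", cmp$name,
             " has no protein pool in the individual", call. = FALSE)
      prod_i <- 0L
      if (!identical(pr$product, "sink")) {
        prod_i <- match(pr$product, names(compounds))
        if (is.na(prod_i))
          stop("product compound '", pr$product, "' of a ", pr$protein,
               " process of ", cmp$name, " is not in the model",
               call. = FALSE)
      }
      for (hi in seq_len(nrow(hosts))) {
        oi <- match(hosts$organ[hi], org$name)
        if (is.na(oi)) next
        dest <- "ic"
        if (pr$kind == "ActiveEffluxMM")
          dest <- c(liver = "bile", `gut wall` = "lumen",
                    kidney = "urine")[[hosts$organ[hi]]]
        procs <- c(procs, list(list(
          protein = pr$protein, kind = pr$kind, organ_i = oi,
          E = hosts$concentration[hi] * Vic[oi],
          conc = hosts$concentration[hi],
          K_M = pr$K_M, k_cat = pr$k_cat, CL_spec = pr$CL_spec,
          product = prod_i, dest = dest)))
      }
    }
    st$procs <- procs
    st$has_bile <- any(vapply(procs, function(p)
      identical(p$dest, "bile"), logical(1)))
    cdoses <- doses[dose_comp == cmp$name]
    st$has_gi <- length(cdoses) > 0 || st$has_bile ||
      any(vapply(procs, function(p) identical(p$dest, "lumen"), logical(1)))
    solid <- Filter(function(d) d$formulation$kind != "solution", cdoses)
    st$has_solid <- length(solid) > 0
    if (st$has_solid) {
      bins <- solid[[1]]$formulation$particle_bins
      dens <- solid[[1]]$formulation$density
      st$bins <- bins
      r0 <- bins$radius * 1e-4
      h <- pmin(r0, .DIFFUSION_LAYER_MAX)
      st$kbin <- 3 * .DIFFUSION_COEF * cmp$MW /
        (dens * 1e3 * r0 * h * 1e6)      # 1/min per (umol/L) gap
    }
    if (st$has_gi) {
      st$Pint <- c(fasted = NA_real_, fed = NA_real_)
      if (!is.null(cmp$intestinal_permeability))
        st$Pint <- c(fasted = unname(cmp$intestinal_permeability["fasted"]),
                     fed = unname(cmp$intestinal_permeability["fed"]))
      # local solubility per segment, umol/L, fasted/fed columns
      st$sol_seg <- apply(pH_seg, 2, function(ph)
        vapply(ph, function(p)
          solubility_at_ph(cmp, p) * 1000 / cmp$MW, numeric(1)))
    }

    pre <- cmp$name
    if (!st$restricted) {
      st$ven <- push(1L, paste0(pre, ".ven"))
      st$art <- push(1L, paste0(pre, ".art"))
      st$ec <- push(12L, paste0(pre, ".ec.", org$name))
    }
    st$ic <- push(12L, paste0(pre, ".ic.", org$name))
    if (st$has_bile) st$bile <- push(1L, paste0(pre, ".bile"))
    if (st$has_gi) st$dis <- push(nseg, paste0(pre, ".dis.", seg$segment))
    if (st$has_solid) {
      nb <- nrow(st$bins)
      st$sol <- matrix(push(nseg * nb,
                            paste0(pre, ".sol.", rep(seg$segment, nb), ".b",
                                   rep(seq_len(nb), each = nseg))),
                       nseg, nb)
    }
    if (!st$restricted) st$led_urine <- push(1L, paste0(pre, ".urine"))
    if (st$has_gi) st$led_feces <- push(1L, paste0(pre, ".feces"))
    if (length(procs)) {
      # one metabolism ledger per distinct metabolic route (efflux routes
      # conserve mass inside tracked states/ledgers already)
      met <- which(vapply(procs, function(p)
        p$kind != "ActiveEffluxMM", logical(1)))
      st$led_met <- integer(length(procs))
      for (k in met) {
        lab <- paste0(pre, ".met.", procs[[k]]$protein, ".",
                      if (procs[[k]]$product > 0)
                        names(compounds)[procs[[k]]$product] else "sink",
                      ".", org$name[procs[[k]]$organ_i])
        st$led_met[k] <- push(1L, lab)
      }
    } else st$led_met <- integer(0)
    cs[[ci]] <- st
  }
  names(cs) <- names(compounds)

  # ---- initial state and dosing events ------------------------------------
  y0 <- stats::setNames(numeric(n), nm_state)
  ev <- list(var = integer(0), time = numeric(0), value = numeric(0))
  for (d in doses) {
    ci <- match(d$compound, names(compounds))
    st <- cs[[ci]]
    amt <- d$dose * 1000 / compounds[[ci]]$MW  # mg -> umol
    tmin <- d$time * 60
    if (d$formulation$kind == "solution") {
      tgt <- st$dis[1]; vals <- amt
    } else {
      tgt <- st$sol[1, ]; vals <- amt * st$bins$mass_fraction
    }
    if (tmin <= 0) {
      y0[tgt] <- y0[tgt] + vals
    } else {
      ev$var <- c(ev$var, tgt)
      ev$time <- c(ev$time, rep(tmin, length(tgt)))
      ev$value <- c(ev$value, vals)
    }
  }
  events <- if (length(ev$var))
    data.frame(var = ev$var, time = ev$time, value = ev$value,
               method = "add") else NULL

  structure(list(
    individual = individual, compounds = compounds, doses = doses,
    scenario = scenario, cs = cs, y0 = y0, events = events,
    pr_t = pr_t, pr_s = pr_s,
    geom = list(V = V, Vec = Vec, Vic = Vic, Q = Q, CO = CO,
                Qliv_tot = Qliv_tot, Vven = Vven, Vart = Vart,
                GFR_L = GFR_L, organ = org$name,
                i_lung = i_lung, i_liv = i_liv, i_kid = i_kid,
                i_gut = i_gut, i_spl = i_spl, i_term = i_term,
                Vlum = Vlum, SAseg = SAseg, ktr = ktr,
                w_efflux = w_efflux, nseg = nseg),
    inh_cyp = inh_cyp, inh_pgp = inh_pgp
  ), class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %d compounds (%s), scenario %s, %d states, %d doses\n",
              length(x$compounds), paste(names(x$compounds), collapse = ", "),
              x$scenario, length(x$y0), length(x$doses)))
  invisible(x)
}

# Derivative function over the model state; `t` in minutes, `y` in umol.
.model_rhs <- function(model) {
  g <- model$geom
  cs <- model$cs
  ncomp <- length(cs)
  pr_t <- model$pr_t; pr_s <- model$pr_s
  inh_cyp <- model$inh_cyp; inh_pgp <- model$inh_pgp
  n <- length(model$y0)
  i_lung <- g$i_lung; i_liv <- g$i_liv; i_kid <- g$i_kid
  i_gut <- g$i_gut; i_spl <- g$i_spl; i_term <- g$i_term
  Qterm <- g$Q[i_term]

  function(t, y, parms) {
    y <- pmax(y, 0)
    dy <- numeric(n)
    pcol <- 1L
    if (length(pr_t)) {
      ii <- findInterval(t, pr_t)
      if (ii > 0L) pcol <- pr_s[ii]
    }

    # intracellular (total and unbound) concentrations, all compounds
    Cic <- matrix(0, ncomp, 12); Cicu <- matrix(0, ncomp, 12)
    for (ci in seq_len(ncomp)) {
      st <- cs[[ci]]
      Cic[ci, ] <- y[st$ic] / g$Vic
      Cicu[ci, ] <- Cic[ci, ] * st$fu / st$Kcu
    }
    fCYP <- rep(1, 12); fPgp <- rep(1, 12)
    for (e in inh_cyp) fCYP <- fCYP + Cicu[e$comp, ] / e$K_i
    for (e in inh_pgp) fPgp <- fPgp + Cicu[e$comp, ] / e$K_i

    dIC <- matrix(0, ncomp, 12)

    for (ci in seq_len(ncomp)) {
      st <- cs[[ci]]
      v_bile_in <- 0; v_lumen_in <- 0

      if (!st$restricted) {
        Cven <- y[st$ven] / g$Vven
        Cart <- y[st$art] / g$Vart
        Cec <- y[st$ec] / g$Vec
        # unbound gradient: extracellular side referenced to blood
        # (fu / blood:plasma ratio), intracellular side to the
        # cell-to-plasma partition coefficient
        J <- st$PS * (st$fu_b * Cec - st$fu * Cic[ci, ] / st$Kcu)
        dAec <- numeric(12)
        dAec[i_lung] <- g$CO * (Cven - Cec[i_lung])
        dAec[i_term] <- Qterm * (Cart - Cec[i_term])
        dAec[i_gut] <- g$Q[i_gut] * (Cart - Cec[i_gut])
        dAec[i_spl] <- g$Q[i_spl] * (Cart - Cec[i_spl])
        dAec[i_liv] <- g$Q[i_liv] * Cart + g$Q[i_gut] * Cec[i_gut] +
          g$Q[i_spl] * Cec[i_spl] - g$Qliv_tot * Cec[i_liv]
        v_ren <- st$gfr_frac * g$GFR_L * st$fu_b * Cec[i_kid]
        dAec[i_kid] <- dAec[i_kid] - v_ren
        dy[st$led_urine] <- dy[st$led_urine] + v_ren
        dAec <- dAec - J
        dy[st$ven] <- sum(Qterm * Cec[i_term]) +
          g$Qliv_tot * Cec[i_liv] - g$CO * Cven
        dy[st$art] <- g$CO * Cec[i_lung] - sum(g$Q) * Cart
        dy[st$ec] <- dAec
        dIC[ci, ] <- dIC[ci, ] + J
      }

      # kinetic processes (metabolism, efflux)
      for (k in seq_along(st$procs)) {
        pr <- st$procs[[k]]
        o <- pr$organ_i
        Cu <- Cicu[ci, o]
        if (pr$kind == "FirstOrderEnzymeNormalized") {
          v <- pr$CL_spec * pr$conc * Cu * g$Vic[o]
        } else {
          fac <- if (pr$protein == "CYP3A4") fCYP[o]
                 else if (pr$protein == "P-gp") fPgp[o] else 1
          v <- pr$k_cat * pr$E * Cu / (pr$K_M * fac + Cu)
        }
        dIC[ci, o] <- dIC[ci, o] - v
        switch(pr$dest,
               ic = { if (pr$product > 0)
                 dIC[pr$product, o] <- dIC[pr$product, o] + v },
               bile = { v_bile_in <- v_bile_in + v },
               lumen = { v_lumen_in <- v_lumen_in + v },
               urine = { dy[st$led_urine] <- dy[st$led_urine] + v })
        if (pr$kind != "ActiveEffluxMM") {
          li <- st$led_met[k]
          dy[li] <- dy[li] + v
        }
      }

      # GI tract
      if (isTRUE(st$has_gi)) {
        dis <- y[st$dis]
        Cdis <- dis / g$Vlum
        kt <- g$ktr[, pcol]
        out <- kt * dis
        ddis <- -out
        ddis[2:g$nseg] <- ddis[2:g$nseg] + out[1:(g$nseg - 1)]
        dy[st$led_feces] <- dy[st$led_feces] + out[g$nseg]
        if (!is.na(st$Pint[pcol])) {
          Jabs <- st$Pint[pcol] * g$SAseg * Cdis / 1000
          ddis <- ddis - Jabs
          dIC[ci, i_gut] <- dIC[ci, i_gut] + sum(Jabs)
        }
        if (isTRUE(st$has_solid)) {
          sol <- matrix(y[st$sol], g$nseg)
          gap <- pmax(st$sol_seg[, pcol] - Cdis, 0)
          R <- sol * outer(gap, st$kbin)
          solout <- kt * sol
          dsol <- -R - solout
          dsol[2:g$nseg, ] <- dsol[2:g$nseg, ] + solout[1:(g$nseg - 1), ]
          dy[st$led_feces] <- dy[st$led_feces] + sum(solout[g$nseg, ])
          ddis <- ddis + rowSums(R)
          dy[st$sol] <- dsol
        }
        if (isTRUE(st$has_bile)) {
          rel <- .BILE_RELEASE_RATE * y[st$bile]
          dy[st$bile] <- v_bile_in - rel
          ddis[2] <- ddis[2] + st$ehc * rel
          dy[st$led_feces] <- dy[st$led_feces] + (1 - st$ehc) * rel
        }
        if (v_lumen_in > 0) ddis <- ddis + g$w_efflux * v_lumen_in
        dy[st$dis] <- ddis
      } else if (st$has_bile) {
        # biliary efflux without a GI tract routes directly to feces
        rel <- .BILE_RELEASE_RATE * y[st$bile]
        dy[st$bile] <- v_bile_in - rel
      }
    }
    for (ci in seq_len(ncomp)) dy[cs[[ci]]$ic] <- dIC[ci, ]
    list(dy)
  }
}
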