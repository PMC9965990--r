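# Delimited-text I/O for observed profiles and metric reports.

#' Write observed profiles as delimited text
#'
#' Long format with columns `study_id`, `compound`, `time_h`,
#' `conc_ng_per_ml` and (when present) `sd`.
#'
#' @param profiles List of [observed_profile()]s.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p)
    data.frame(study_id = p$study_id, compound = p$compound,
               time_h = p$times, conc_ng_per_ml = p$conc,
               sd = if (is.null(p$sd)) NA_real_ else p$sd))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read observed profiles from delimited text
#'
#' Inverse of [write_profiles()]; regimen metadata is not part of the text
#' format and must be attached separately for fitting.
#'
#' @param path Tab-separated file with `study_id`, `compound`, `time_h`,
#'   `conc_ng_per_ml` and optional `sd` columns.
#' @return List of [observed_profile()]s.
#' @export
read_profiles <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("study_id", "compound", "time_h", "conc_ng_per_ml")
  if (!all(need %in% names(df)))
    stop("profile table lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  keys <- unique(df[, c("study_id", "compound")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$study_id == keys$study_id[i] &
                df$compound == keys$compound[i], ]
    sub <- sub[order(sub$time_h), ]
    sdv <- if ("sd" %in% names(sub) && !all(is.na(sub$sd))) sub$sd else NULL
    observed_profile(keys$study_id[i], keys$compound[i], sub$time_h,
                     sub$conc_ng_per_ml, sd = sdv)
  })
}

#' Evaluate predictions against observed profiles
#'
#' Computes the per-profile and pooled mean relative deviation and, from
#' the per-profile PK parameters, the geometric mean fold errors of
#' AUC_last and C_max, mirroring the standard goodness-of-prediction
#' workflow.
#'
#' @param observed List of [observed_profile()]s.
#' @param predicted List of matching profiles (same study/compound/times):
#'   either `observed_profile`s or data frames with `time_h` and
#'   `conc_ng_per_ml`.
#' @return List with `per_profile` data frame (`study_id`, `compound`,
#'   `mrd`, AUC/Cmax pairs), `mrd_overall`, `gmfe_auc`, `gmfe_cmax`, and
#'   `within_twofold` counts.
#' @export
evaluate_predictions <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  rows <- list(); all_o <- numeric(0); all_p <- numeric(0)
  for (i in seq_along(observed)) {
    o <- observed[[i]]; p <- predicted[[i]]
    pt <- if (inherits(p, "observed_profile")) p$times else p$time_h
    pc <- if (inherits(p, "observed_profile")) p$conc else p$conc_ng_per_ml
    pc <- stats::approx(pt, pc, xout = o$times)$y
    keep <- o$conc > 0 & pc > 0
    rows[[i]] <- data.frame(
      study_id = o$study_id, compound = o$compound,
      mrd = mrd(o$conc[keep], pc[keep]),
      auc_obs = auc_last(o$times, o$conc), auc_pred = auc_last(o$times, pc),
      cmax_obs = max(o$conc), cmax_pred = max(pc))
    all_o <- c(all_o, o$conc[keep]); all_p <- c(all_p, pc[keep])
  }
  per <- do.call(rbind, rows)
  list(per_profile = per,
       mrd_overall = mrd(all_o, all_p),
       gmfe_auc = gmfe(per$auc_obs, per$auc_pred),
       gmfe_cmax = gmfe(per$cmax_obs, per$cmax_pred),
       within_twofold = c(
         auc = sum(mapply(within_twofold, per$auc_pred, per$auc_obs)),
         cmax = sum(mapply(within_twofold, per$cmax_pred, per$cmax_obs)),
         n = nrow(per)))
}
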