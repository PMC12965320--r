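#' Aggregate per-neuron records into per-well outcome parameters
#'
#' The well is the technical-replicate unit fed to statistics. For each
#' well: neuron counts by population, the percentage of GVB+ neurons
#' (`100 * n_gvb_pos / denominator`; the denominator mode - tau+ neurons
#' or GFP+ neurons - is recorded), the accepted GVB clusters per 100
#' neurons (the per-cluster counting convention, reported alongside the
#' per-neuron one), the tau+/tau- survival ratio, and the
#' mean of every requested per-neuron value column within each population
#' (tau-, tau+/GVB-, tau+/GVB+).
#'
#' @param neurons the `neurons` table of [analyze_plate()].
#' @param value_cols per-neuron columns to average per population
#'   (default: all `somatic_*` and `nuccorr_*` columns).
#' @param denominator `"tau_pos"` (GVB+ among tau+ neurons) or
#'   `"gfp_pos"` (GVB+/GFP+ among GFP+ neurons, requiring a
#'   `gfp_positive` column).
#' @return Data frame of class `well_summary`, one row per well.
#' @export
aggregate_wells <- function(neurons,
                            value_cols = grep("^(somatic|nuccorr)_",
                                              names(neurons), value = TRUE),
                            denominator = c("tau_pos", "gfp_pos")) {
  denominator <- match.arg(denominator)
  if (denominator == "gfp_pos" && is.null(neurons$gfp_positive))
    stop("gfp_pos denominator requires a `gfp_positive` column",
         call. = FALSE)
  wells <- unique(neurons[c("well", "condition", "replicate")])
  rownames(wells) <- NULL
  out <- lapply(seq_len(nrow(wells)), function(i) {
    nw <- neurons[neurons$well == wells$well[i], , drop = FALSE]
    n_tau_pos <- sum(nw$tau_status, na.rm = TRUE)
    n_tau_neg <- sum(!nw$tau_status, na.rm = TRUE)
    if (denominator == "tau_pos") {
      denom <- n_tau_pos
      n_gvb <- sum(nw$tau_status & nw$gvb_status == "GVB+", na.rm = TRUE)
    } else {
      denom <- sum(nw$gfp_positive, na.rm = TRUE)
      n_gvb <- sum(nw$gfp_positive & nw$gvb_status == "GVB+", na.rm = TRUE)
    }
    row <- data.frame(
      well = wells$well[i], condition = wells$condition[i],
      replicate = wells$replicate[i], n_neurons = nrow(nw),
      n_tau_pos = n_tau_pos, n_tau_neg = n_tau_neg, n_gvb_pos = n_gvb,
      denominator = denominator,
      pct_gvb_pos = if (denom > 0) 100 * n_gvb / denom else NA_real_,
      # the per-cluster counting convention: accepted GVB clusters per
      # 100 neurons in the well (reported alongside the per-neuron mode)
      pct_gvb_clusters = if (nrow(nw) > 0 &&
                               !is.null(nw$n_gvb_clusters))
        100 * sum(nw$n_gvb_clusters, na.rm = TRUE) / nrow(nw) else
          NA_real_,
      survival_ratio = if (n_tau_neg > 0) n_tau_pos / n_tau_neg else
        NA_real_)
    for (pop in c("tau_neg", "gvb_neg", "gvb_pos")) {
      sel <- nw$population == pop
      for (vc in value_cols)
        row[[paste0("mean_", pop, "_", vc)]] <-
          if (any(sel)) mean(nw[[vc]][sel], na.rm = TRUE) else NA_real_
    }
    row
  })
  out <- do.call(rbind, out)
  class(out) <- c("well_summary", "data.frame")
  out
}

#' Normalise well summaries to the mean of the control wells
#'
#' Each value column is divided by the mean of the control-condition wells
#' within the same normalisation stratum (e.g. per time point), so the
#' control stratum mean maps to exactly 1. Normalising an already
#' normalised table with the same strata is the identity.
#'
#' @param wells a `well_summary` (or any data frame with a `condition`
#'   column).
#' @param control_condition condition label of the control wells.
#' @param value_cols columns to normalise (default `pct_gvb_pos`).
#' @param strata optional column name(s) defining normalisation strata
#'   (e.g. `"time"`); `NULL` normalises globally.
#' @return `wells` with an added `<col>_norm` column per value column.
#' @export
normalize_to_control <- function(wells, control_condition,
                                 value_cols = "pct_gvb_pos",
                                 strata = NULL) {
  key <- if (is.null(strata)) rep("all", nrow(wells)) else
    interaction(wells[strata], drop = TRUE)
  for (vc in value_cols) wells[[paste0(vc, "_norm")]] <- NA_real_
  for (s in unique(key)) {
    in_s <- key == s
    ctrl <- in_s & wells$condition == control_condition
    if (!any(ctrl))
      stop(sprintf("no '%s' control wells in normalisation stratum '%s'",
                   control_condition, s), call. = FALSE)
    for (vc in value_cols) {
      ref <- mean(wells[[vc]][ctrl], na.rm = TRUE)
      wells[[paste0(vc, "_norm")]][in_s] <- wells[[vc]][in_s] / ref
    }
  }
  wells
}

#' Population survival ratio of a well
#'
#' Count of a neuron population divided by the tau- neuron count of the
#' same well (the tau- population serves as the internal reference that
#' the counts are "normalised to"); downstream, ratios are normalised to
#' the control condition with [normalize_to_control()].
#'
#' @param n_population neuron count of the population of interest.
#' @param n_tau_neg tau- neuron count of the same well (> 0).
#' @return The ratio.
#' @export
survival_ratio <- function(n_population, n_tau_neg) {
  if (any(n_tau_neg <= 0))
    stop("survival ratio undefined for wells with no tau- neurons",
         call. = FALSE)
  n_population / n_tau_neg
}
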