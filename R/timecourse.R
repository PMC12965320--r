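#' Define the ground truth of a GVB formation/loss time course
#'
#' The control arm follows a non-decreasing piecewise-linear trajectory of
#' the GVB+ fraction over days in culture. A treatment starting at `t0`
#' completely blocks new GVB formation, so the treated arm only retains the
#' GVB+ neurons existing at `t0`, lost exponentially with half-life
#' `half_life`: `G(t0) * 2^(-(t - t0)/half_life)`.
#'
#' @param times,fractions the control trajectory (days; % GVB+ in [0, 100]).
#'   Defaults follow a culture where the first GVBs appear around day 13,
#'   about 10% of tau+ neurons are GVB+ at day 15 and 34% by day 29.
#' @param t0 treatment start (days), inside the control time range.
#' @param half_life true half-life of the GVB+ state under a formation
#'   block (days), must be positive.
#' @param obs_times observation times of the treated arm (days); at least
#'   one must lie after `t0`.
#' @param noise_sd replicate noise as a fraction of the sampled value.
#' @return An object of class `kinetic_truth`.
#' @export
kinetic_truth <- function(times = c(8, 13, 15, 22, 29),
                          fractions = c(0, 2, 10, 26, 34),
                          t0 = 20, half_life = 5.4,
                          obs_times = c(22, 28), noise_sd = 0) {
  if (length(times) != length(fractions) || is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing and match `fractions`",
         call. = FALSE)
  if (any(diff(fractions) < 0))
    stop("the control trajectory must be non-decreasing", call. = FALSE)
  if (any(fractions < 0 | fractions > 100))
    stop("fractions must lie in [0, 100]", call. = FALSE)
  if (half_life <= 0) stop("`half_life` must be positive", call. = FALSE)
  if (t0 < min(times) || t0 > max(times))
    stop("`t0` must lie inside the control time range", call. = FALSE)
  if (!any(obs_times > t0))
    stop("at least one observation time must lie after `t0`", call. = FALSE)
  structure(list(times = times, fractions = fractions, t0 = t0,
                 half_life = half_life, obs_times = obs_times,
                 noise_sd = noise_sd),
            class = "kinetic_truth")
}

#' Sample replicate GVB+ fraction series from a kinetic truth
#'
#' Control-arm replicates sample the control trajectory plus relative
#' Gaussian noise; treated-arm replicates sample
#' `G(t0) * 2^(-(t - t0)/half_life)` plus noise, truncated at 0.
#'
#' @param truth a [kinetic_truth()].
#' @param n_replicates replicates per time point and arm.
#' @param seed integer seed.
#' @return A long-format data frame with columns `time`, `arm`
#'   (`"control"`/`"treated"`), `replicate`, `fraction`, carrying `t0` as an
#'   attribute.
#' @export
generate_timecourse <- function(truth, n_replicates = 3L, seed = 1L) {
  if (!inherits(truth, "kinetic_truth"))
    stop("`truth` must be a kinetic_truth", call. = FALSE)
  with_seed(seed, {
    g <- function(t) stats::approx(truth$times, truth$fractions, t)$y
    g0 <- g(truth$t0)
    rows <- list()
    for (t in truth$times)
      rows[[length(rows) + 1L]] <- data.frame(
        time = t, arm = "control", replicate = seq_len(n_replicates),
        fraction = noisy(g(t), truth$noise_sd, n_replicates))
    for (t in truth$obs_times) {
      mu <- if (t <= truth$t0) g(t) else
        g0 * 2^(-(t - truth$t0) / truth$half_life)
      rows[[length(rows) + 1L]] <- data.frame(
        time = t, arm = "treated", replicate = seq_len(n_replicates),
        fraction = noisy(mu, truth$noise_sd, n_replicates))
    }
    out <- do.call(rbind, rows)
    attr(out, "t0") <- truth$t0
    out
  })
}

noisy <- function(mu, sd_rel, n) {
  pmax(mu * (1 + stats::rnorm(n, 0, sd_rel)), 0)
}
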