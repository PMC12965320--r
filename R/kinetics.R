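#' Expected GVB+ fraction at treatment start
#'
#' Under a complete block of new GVB formation, the GVB+ neurons observed
#' after treatment must have existed at treatment start; the "expected"
#' fraction is therefore the control-arm GVB+ fraction at `t0`, linearly
#' interpolated between the flanking control observations (replicate means
#' are interpolated and the standard error is propagated accordingly).
#'
#' @param series long-format data frame with columns `time`, `arm`,
#'   `replicate`, `fraction` (see [generate_timecourse()]).
#' @param t0 treatment start in days (defaults to the series' `t0`
#'   attribute); must lie inside the control time range.
#' @return The interpolated fraction, with attribute `"se"`.
#' @export
expected_at_start <- function(series, t0 = attr(series, "t0")) {
  ctrl <- series[series$arm == "control", , drop = FALSE]
  if (!nrow(ctrl)) stop("series has no control arm", call. = FALSE)
  tms <- sort(unique(ctrl$time))
  if (is.null(t0) || t0 < min(tms) || t0 > max(tms))
    stop("`t0` outside the control time range", call. = FALSE)
  mns <- tapply(ctrl$fraction, ctrl$time, mean)[as.character(tms)]
  ses <- tapply(ctrl$fraction, ctrl$time,
                function(z) stats::sd(z) / sqrt(length(z)))[as.character(tms)]
  if (t0 %in% tms) {
    i <- which(tms == t0)
    return(structure(unname(mns[i]), se = unname(ses[i])))
  }
  i <- findInterval(t0, tms)
  w <- (t0 - tms[i]) / (tms[i + 1L] - tms[i])
  est <- (1 - w) * mns[i] + w * mns[i + 1L]
  se <- sqrt(((1 - w) * ses[i])^2 + (w * ses[i + 1L])^2)
  structure(unname(est), se = unname(se))
}

#' Estimate the GVB half-life from expected versus observed fractions
#'
#' For every treated observation at offset `dt = t - t0`, the retention
#' `r = observed / expected` gives a per-offset half-life
#' `t_half = dt * log(2) / log(1/r)` under exponential loss; the reported
#' half-life is the arithmetic mean of the per-offset estimates (the
#' `"joint"` mode instead fits `log r ~ dt` through the origin). The
#' expected fraction is the control fraction at treatment start
#' (`expected = "start"`, the default: with a complete formation block
#' only pre-existing GVB+ neurons remain observable) or the
#' contemporaneous control (`expected = "contemporaneous"`). Offsets with
#' `r >= 1` show no detectable decay and are excluded with a warning;
#' if every offset is excluded, or any retention is non-positive, the
#' estimator stops.
#'
#' @param series long-format series as in [expected_at_start()].
#' @param t0 treatment start (days).
#' @param mode `"per_offset"` (default) or `"joint"`.
#' @param expected `"start"` or `"contemporaneous"`.
#' @return Object of class `halflife_fit`: per-offset estimates,
#'   retentions, the average `t_half`, diagnostics.
#' @examples
#' tc <- generate_timecourse(kinetic_truth(half_life = 5.4), seed = 1)
#' fit <- estimate_halflife(tc)
#' coef(fit)
#' @export
estimate_halflife <- function(series, t0 = attr(series, "t0"),
                              mode = c("per_offset", "joint"),
                              expected = c("start", "contemporaneous")) {
  mode <- match.arg(mode)
  expected <- match.arg(expected)
  trt <- series[series$arm == "treated" & series$time > t0, , drop = FALSE]
  if (!nrow(trt))
    stop("no treated observations after `t0`", call. = FALSE)
  e0 <- expected_at_start(series, t0)
  tms <- sort(unique(trt$time))
  obs <- tapply(trt$fraction, trt$time, mean)[as.character(tms)]
  exp_f <- if (expected == "start") rep(as.numeric(e0), length(tms)) else
    vapply(tms, function(t) {
      ct <- series$fraction[series$arm == "control" & series$time == t]
      if (length(ct)) mean(ct) else as.numeric(expected_at_start(series, t))
    }, numeric(1))
  r <- unname(obs / exp_f)
  if (any(r <= 0))
    stop("non-positive retention; cannot take logarithms", call. = FALSE)
  usable <- r < 1
  if (!any(usable))
    stop("all retentions >= 1: no decay signal in the treated arm",
         call. = FALSE)
  if (any(!usable))
    warning(sprintf("excluding %d offset(s) with retention >= 1 (no decay)",
                    sum(!usable)), call. = FALSE)
  dt <- tms - t0
  per_offset <- ifelse(usable, -dt * log(2) / log(r), NA_real_)
  t_half <- if (mode == "per_offset") mean(per_offset[usable]) else
    -log(2) / unname(stats::lm.fit(cbind(dt[usable]),
                                   log(r[usable]))$coefficients)
  structure(list(
    t_half = t_half, mode = mode, expected = expected,
    per_offset = data.frame(time = tms, offset_days = dt, observed = obs,
                            expected = exp_f, retention = r,
                            t_half = per_offset, used = usable),
    expected_at_start = as.numeric(e0), t0 = t0,
    n_points = sum(usable)), class = "halflife_fit")
}

#' @export
print.halflife_fit <- function(x, ...) {
  cat(sprintf(
    "GVB half-life fit (%s, expected = %s): t1/2 = %.3g days (%d offset%s)\n",
    x$mode, x$expected, x$t_half, x$n_points,
    if (x$n_points == 1L) "" else "s"))
  invisible(x)
}

#' @export
summary.halflife_fit <- function(object, ...) {
  print(object)
  cat(sprintf("expected GVB+ fraction at t0 = %g days: %.3f\n",
              object$t0, object$expected_at_start))
  print(object$per_offset, row.names = FALSE)
  invisible(object)
}

#' @export
coef.halflife_fit <- function(object, ...) c(t_half = object$t_half)
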