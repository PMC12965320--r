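#' Nested t test on technical-within-biological replicates
#'
#' Technical replicates are first collapsed to unweighted
#' biological-replicate means (each biological replicate counts once,
#' regardless of how many wells it contains); the default mode then runs a
#' pooled-variance two-sample t test on those means, so the degrees of
#' freedom reflect biological replicates, never wells. The `"lmm"` mode
#' instead fits a random-intercept mixed model on the raw technical
#' replicates (closer to a variance-components nested t; requires
#' lmerTest).
#'
#' A biological replicate id appearing in both groups is a design
#' violation and an error; duplicating every technical replicate changes
#' nothing (collapse invariance).
#'
#' @param data data frame of technical replicates.
#' @param group_a,group_b the two condition labels to compare.
#' @param value,group,bio column names of the value, condition and
#'   biological-replicate id.
#' @param mode `"means"` (default) or `"lmm"`.
#' @return Object of class `nested_test`: `statistic`, `df`, `p_value`,
#'   `group_means`, `method`, `degenerate`.
#' @export
nested_t <- function(data, group_a, group_b, value = "value",
                     group = "condition", bio = "replicate",
                     mode = c("means", "lmm")) {
  mode <- match.arg(mode)
  d <- data[data[[group]] %in% c(group_a, group_b), , drop = FALSE]
  shared <- intersect(unique(d[[bio]][d[[group]] == group_a]),
                      unique(d[[bio]][d[[group]] == group_b]))
  if (length(shared))
    stop(sprintf(paste0("biological replicate(s) %s appear in both groups; ",
                        "use group-specific replicate ids"),
                 paste(shared, collapse = ", ")), call. = FALSE)
  ma <- collapse_bio(d, group_a, value, group, bio)
  mb <- collapse_bio(d, group_b, value, group, bio)
  if (length(ma) < 2L || length(mb) < 2L)
    stop("need at least two biological replicates per group", call. = FALSE)

  if (mode == "lmm") {
    if (!requireNamespace("lmerTest", quietly = TRUE))
      stop("mode = 'lmm' requires the lmerTest package", call. = FALSE)
    d$..g <- factor(d[[group]], levels = c(group_a, group_b))
    fit <- lmerTest::lmer(stats::reformulate(
      c("..g", sprintf("(1 | %s)", bio)), response = value), data = d)
    co <- stats::coef(summary(fit))[2L, ]
    return(new_nested_test(co[["t value"]], co[["df"]], co[["Pr(>|t|)"]],
                           c(mean(ma), mean(mb)), c(group_a, group_b),
                           "nested t (random-intercept mixed model)"))
  }
  tt <- two_sample_t(ma, mb)
  new_nested_test(tt$t, tt$df, tt$p, c(mean(ma), mean(mb)),
                  c(group_a, group_b),
                  "nested t (biological-replicate means)",
                  degenerate = tt$degenerate)
}

collapse_bio <- function(d, g, value, group, bio) {
  dg <- d[d[[group]] == g, , drop = FALSE]
  as.numeric(tapply(dg[[value]], dg[[bio]], mean))
}

# Pooled-variance two-sample t with explicit degenerate handling: equal
# groups with zero variance give t = 0, p = 1 rather than an error.
two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  df <- na + nb - 2L
  sp2 <- ((na - 1L) * stats::var(a) + (nb - 1L) * stats::var(b)) / df
  diff <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (diff == 0) return(list(t = 0, df = df, p = 1, degenerate = FALSE))
    return(list(t = sign(diff) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  t <- diff / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

new_nested_test <- function(stat, df, p, means, groups, method,
                            degenerate = FALSE) {
  structure(list(statistic = unname(stat), df = unname(df),
                 p_value = unname(p),
                 group_means = stats::setNames(means, groups),
                 method = method, degenerate = degenerate),
            class = "nested_test")
}

#' @export
print.nested_test <- function(x, ...) {
  cat(sprintf("%s\n  t = %.4g, df = %.3g, p = %.4g%s\n", x$method,
              x$statistic, x$df, x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate: zero variance)" else ""))
  cat("  group means:",
      paste(sprintf("%s = %.4g", names(x$group_means), x$group_means),
            collapse = ", "), "\n")
  invisible(x)
}

#' Nested one-way ANOVA with Dunnett or Sidak post hoc
#'
#' One-way ANOVA on biological-replicate means (technical replicates
#' collapsed as in [nested_t()]), followed by either Dunnett's test of
#' every group against a reference (via multcomp) or Sidak-adjusted
#' pairwise comparisons (`p_adj = 1 - (1 - p)^m` over the declared family,
#' pooled-variance t statistics on the ANOVA residual variance).
#'
#' @inheritParams nested_t
#' @param posthoc `"dunnett"` or `"sidak"`.
#' @param reference reference condition (required for Dunnett).
#' @return List of class `nested_anova`: `anova` (F, dfs, p) and
#'   `comparisons` (estimate, raw and adjusted p per comparison).
#' @export
nested_anova <- function(data, value = "value", group = "condition",
                         bio = "replicate",
                         posthoc = c("dunnett", "sidak"),
                         reference = NULL) {
  posthoc <- match.arg(posthoc)
  if (posthoc == "dunnett" && is.null(reference))
    stop("Dunnett's post hoc needs a `reference` condition", call. = FALSE)
  groups <- unique(as.character(data[[group]]))
  bg <- unique(data.frame(g = as.character(data[[group]]), b = data[[bio]]))
  if (anyDuplicated(bg$b))
    stop("a biological replicate id appears in more than one group",
         call. = FALSE)
  means <- do.call(rbind, lapply(groups, function(g)
    data.frame(g = g, m = collapse_bio(data, g, value, group, bio))))
  if (any(table(means$g) < 2L))
    stop("need at least two biological replicates per group", call. = FALSE)
  means$g <- factor(means$g,
                    levels = c(if (!is.null(reference)) reference,
                               setdiff(groups, reference)))
  fit <- stats::aov(m ~ g, data = means)
  an <- summary(fit)[[1L]]
  mse <- an["Residuals", "Mean Sq"]
  Fv <- an["g", "F value"]; pF <- an["g", "Pr(>F)"]
  # all groups numerically identical: 0/0 noise, report no effect
  if (!is.finite(Fv) ||
      an["g", "Sum Sq"] <= 1e-10 * (1 + mean(means$m)^2)) {
    Fv <- 0; pF <- 1
  }

  gm <- tapply(means$m, means$g, mean)
  gn <- tapply(means$m, means$g, length)
  df_res <- an["Residuals", "Df"]
  comparisons <- if (posthoc == "dunnett") {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(gl)
    data.frame(comparison = names(sm$test$coefficients),
               estimate = unname(sm$test$coefficients),
               p_raw = 2 * stats::pt(-abs(unname(sm$test$tstat)), df_res),
               p_adj = unname(as.numeric(sm$test$pvalues)))
  } else {
    prs <- utils::combn(levels(means$g), 2L)
    m <- ncol(prs)
    do.call(rbind, lapply(seq_len(m), function(i) {
      a <- prs[1L, i]; b <- prs[2L, i]
      est <- gm[[b]] - gm[[a]]
      se <- sqrt(mse * (1 / gn[[a]] + 1 / gn[[b]]))
      p <- if (se > 0) 2 * stats::pt(-abs(est / se), df_res) else
        as.numeric(est == 0)
      data.frame(comparison = paste(b, "-", a), estimate = est,
                 p_raw = p, p_adj = 1 - (1 - p)^m)
    }))
  }
  comparisons$p_adj <- pmax(comparisons$p_adj, comparisons$p_raw)
  structure(list(anova = data.frame(F = Fv, df1 = an["g", "Df"],
                                    df2 = df_res, p_value = pF),
                 comparisons = comparisons, posthoc = posthoc,
                 group_means = gm),
            class = "nested_anova")
}

#' @export
print.nested_anova <- function(x, ...) {
  cat(sprintf("nested one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p_value))
  cat(sprintf("%s post hoc:\n", x$posthoc))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Paired t test on per-well population pairs
#'
#' For comparisons of two populations measured within the same wells
#' (e.g. tau+/GVB- versus tau+/GVB+ neurons of one well). Wells missing
#' either population are excluded with a warning. A constant within-pair
#' difference with zero variance yields an infinite t flagged as
#' degenerate.
#'
#' @param data data frame with one value per well and population.
#' @param pop_a,pop_b the two population labels.
#' @param value,pop,pairing column names (value, population, well id).
#' @return A `nested_test`-classed result (statistic, df, p, means).
#' @export
paired_t <- function(data, pop_a, pop_b, value = "value",
                     pop = "population", pairing = "well") {
  a <- data[data[[pop]] == pop_a, c(pairing, value)]
  b <- data[data[[pop]] == pop_b, c(pairing, value)]
  m <- merge(a, b, by = pairing, suffixes = c("_a", "_b"))
  n_drop <- length(union(a[[pairing]], b[[pairing]])) - nrow(m)
  if (n_drop > 0)
    warning(sprintf("excluding %d unpaired well(s)", n_drop), call. = FALSE)
  if (nrow(m) < 2L) stop("fewer than two complete pairs", call. = FALSE)
  dif <- m[[paste0(value, "_a")]] - m[[paste0(value, "_b")]]
  sdd <- stats::sd(dif)
  df <- nrow(m) - 1L
  if (sdd == 0) {
    if (mean(dif) == 0)
      return(new_nested_test(0, df, 1, c(mean(m[[2L]]), mean(m[[3L]])),
                             c(pop_a, pop_b), "paired t"))
    return(new_nested_test(sign(mean(dif)) * Inf, df, 0,
                           c(mean(m[[2L]]), mean(m[[3L]])),
                           c(pop_a, pop_b), "paired t", degenerate = TRUE))
  }
  t <- mean(dif) / (sdd / sqrt(nrow(m)))
  new_nested_test(t, df, 2 * stats::pt(-abs(t), df),
                  c(mean(m[[2L]]), mean(m[[3L]])), c(pop_a, pop_b),
                  "paired t")
}

#' Robust outlier flagging of technical replicates
#'
#' Robust z scores around the median, scaled by the 68.27th percentile of
#' the absolute residuals with an `n/(n-1)` small-sample correction (a
#' lower-variance robust scale than the MAD), converted to t-distribution
#' tail probabilities and cut at a Benjamini-Hochberg FDR of `Q` percent.
#' This is an openly approximate, location-only analogue of the
#' robust-regression outlier procedure of common GraphPad workflows;
#' exact numerical agreement with that proprietary method is not claimed.
#' Flags are invariant to affine rescaling of the values. Fewer than 5
#' values: no flagging, with a warning.
#'
#' @param values numeric vector.
#' @param Q FDR threshold in percent (default 1).
#' @return Logical vector of flags.
#' @export
flag_outliers <- function(values, Q = 1) {
  n <- length(values)
  if (n < 5L) {
    warning("fewer than 5 values: outlier flagging skipped", call. = FALSE)
    return(rep(FALSE, n))
  }
  med <- stats::median(values)
  s <- stats::quantile(abs(values - med), 0.6827, names = FALSE) *
    n / (n - 1)
  if (s == 0) return(values != med)
  z <- abs(values - med) / s
  p <- 2 * stats::pt(-z, df = n - 1L)
  stats::p.adjust(p, method = "BH") < Q / 100
}
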