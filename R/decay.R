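#' Log10 abundance ratio
#'
#' Transforms a concentration pair into `log10(ct / c0)` — the quantity the
#' decay regressions are fitted on. Negative values indicate decay.
#'
#' @param ct Concentration at time t (> 0). Vectorized.
#' @param c0 Initial concentration (> 0). Vectorized.
#' @return `log10(ct / c0)`.
#' @examples
#' log_ratio(1.31e5, 3.30e6)  # about -1.40
#' @export
log_ratio <- function(ct, c0) {
  if (any(!is.finite(ct)) || any(!is.finite(c0)) || any(ct <= 0) || any(c0 <= 0))
    stop_values("log_ratio requires positive finite concentrations")
  log10(ct / c0)
}

#' Fit a log-linear decay segment
#'
#' Ordinary least squares of `log_ratios` on `days`. The decimal reduction
#' time (D-value: days per 1-log10 decrease) is `abs(1/slope)` for a negative
#' slope and `Inf` otherwise.
#'
#' @param days Numeric vector of days (at least two distinct values).
#' @param log_ratios Numeric vector of log10(Ct/C0) values, same length.
#' @param segment_label Label stored with the fit (`"single"`, `"phase I"`, ...).
#' @return A one-row data frame of class `decay_fit`: `segment`, `day_min`,
#'   `day_max`, `slope` (log10/day), `intercept`, `r_squared`, `d_value`
#'   (days), `n_points`.
#' @examples
#' fit_linear_decay(c(0, 7, 14), c(0, -1, -2))  # D-value 7
#' @export
fit_linear_decay <- function(days, log_ratios, segment_label = "single") {
  keep <- is.finite(days) & is.finite(log_ratios)
  days <- days[keep]; log_ratios <- log_ratios[keep]
  if (length(days) < 2L) stop_values("need at least 2 points to fit decay")
  if (length(unique(days)) < 2L) stop_values("need at least 2 distinct days")
  fit <- stats::lm(log_ratios ~ days)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  tss <- sum((log_ratios - mean(log_ratios))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  structure(data.frame(
    segment = segment_label,
    day_min = min(days), day_max = max(days),
    slope = slope, intercept = intercept, r_squared = r2,
    d_value = if (slope < 0) abs(1 / slope) else Inf,
    n_points = length(days),
    stringsAsFactors = FALSE
  ), class = c("decay_fit", "data.frame"))
}

#' Fit a biphasic (two-segment) decay curve
#'
#' Fits independent log-linear regressions before and after a breakpoint.
#' Days up to and including the breakpoint form phase I; later days phase II.
#' With `breakpoint_day = NULL` the breakpoint is grid-searched over the
#' observed days (leaving at least two points in each segment), choosing the
#' candidate minimizing the total residual sum of squares.
#'
#' @param days,log_ratios As in [fit_linear_decay()].
#' @param breakpoint_day Fixed breakpoint in days, or `NULL` to grid-search.
#' @return A two-row `decay_fit` data frame (phase I, phase II) with an
#'   attribute `breakpoint` giving the breakpoint used.
#' @examples
#' d <- c(0, 4, 8, 12, 15, 20, 30, 40)
#' y <- ifelse(d <= 15, -d / 7, -15 / 7 - (d - 15) / 50)
#' fit_biphasic(d, y, 15)
#' @export
fit_biphasic <- function(days, log_ratios, breakpoint_day = 15) {
  ord <- order(days)
  days <- days[ord]; log_ratios <- log_ratios[ord]
  rss_at <- function(bp) {
    i1 <- days <= bp
    f1 <- stats::lm(log_ratios[i1] ~ days[i1])
    f2 <- stats::lm(log_ratios[!i1] ~ days[!i1])
    sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2)
  }
  if (is.null(breakpoint_day)) {
    cand <- unique(days)
    cand <- cand[vapply(cand, function(b)
      sum(days <= b) >= 2 && sum(days > b) >= 2, logical(1))]
    if (length(cand) == 0L) stop_values("no admissible breakpoint candidates")
    breakpoint_day <- cand[which.min(vapply(cand, rss_at, numeric(1)))]
  }
  if (breakpoint_day < min(days) || breakpoint_day >= max(days))
    stop_values("breakpoint %g outside the observed day range", breakpoint_day)
  i1 <- days <= breakpoint_day
  if (sum(i1) < 2L || sum(!i1) < 2L)
    stop_values("each segment needs at least 2 points (breakpoint %g)",
                breakpoint_day)
  out <- rbind(
    fit_linear_decay(days[i1], log_ratios[i1], "phase I"),
    fit_linear_decay(days[!i1], log_ratios[!i1], "phase II")
  )
  attr(out, "breakpoint") <- breakpoint_day
  out
}

#' Removal efficiency
#'
#' Percentage of the initial concentration removed: `100 * (1 - ct / c0)`.
#' Negative values indicate net growth.
#'
#' @param c0 Initial concentration (> 0). @param ct Final concentration (>= 0).
#' @return Percent removed. Vectorized.
#' @examples
#' removal_efficiency(3.30e6, 1.63e5)  # 95.1
#' @export
removal_efficiency <- function(c0, ct) {
  if (any(c0 <= 0)) stop_values("c0 must be > 0")
  if (any(ct < 0)) stop_values("ct must be >= 0")
  100 * (1 - ct / c0)
}

#' Abundance ratio between treatments
#'
#' `100 * a / b`: the abundance in one treatment as a percentage of another.
#'
#' @param treatment_a_ct Numerator concentration (>= 0).
#' @param treatment_b_ct Denominator concentration (> 0).
#' @return Percent. Vectorized.
#' @examples
#' abundance_ratio(2.08e5, 4.70e5)  # 44.3
#' @export
abundance_ratio <- function(treatment_a_ct, treatment_b_ct) {
  if (any(treatment_b_ct <= 0)) stop_values("denominator must be > 0")
  100 * treatment_a_ct / treatment_b_ct
}

#' Compare group abundances (one-way ANOVA + Tukey HSD)
#'
#' One-way analysis of variance followed by Tukey honest significant
#' difference pairwise comparisons, with significance marks at 0.05 (`*`)
#' and 0.01 (`**`). Used to compare marker-gene abundances between
#' treatments at a time point or phase.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor or character vector of group labels, same length;
#'   at least two groups with at least two observations each.
#' @return A list of class `group_comparison`: `means` (mean and sd per
#'   group), `anova_p`, `pairwise` (data frame with `comparison`, `diff`,
#'   `p_adj`, `signif`).
#' @examples
#' compare_groups(c(1, 1.1, 0.9, 5, 5.2, 4.8), rep(c("NT", "CT"), each = 3))
#' @export
compare_groups <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop_values("need at least 2 groups")
  n <- table(groups)
  if (any(n < 2L)) stop_values("every group needs at least 2 observations")
  means <- data.frame(
    group = levels(groups),
    mean = as.numeric(tapply(values, groups, mean)),
    sd = as.numeric(tapply(values, groups, stats::sd)),
    n = as.integer(n),
    stringsAsFactors = FALSE
  )
  fit <- stats::aov(values ~ groups)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$groups
  pw <- data.frame(
    comparison = rownames(tk),
    diff = tk[, "diff"],
    p_adj = tk[, "p adj"],
    stringsAsFactors = FALSE
  )
  pw$signif <- ifelse(pw$p_adj < 0.01, "**", ifelse(pw$p_adj < 0.05, "*", ""))
  rownames(pw) <- NULL
  structure(list(means = means, anova_p = anova_p, pairwise = pw),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA p = %.4g; Tukey HSD pairwise:\n", x$anova_p))
  print(x$pairwise, ...)
  invisible(x)
}

#' Fit decay curves across an abundance table
#'
#' Convenience wrapper running [fit_biphasic()] (or [fit_linear_decay()]
#' when `breakpoint_day = NA`) for every treatment x gene combination of an
#' abundance table. Log ratios use the day-0 concentration of the same
#' replicate as C0. Below-detection records (zero or missing concentration)
#' are excluded from the regressions.
#'
#' @param abundance Abundance data frame as produced by [make_experiment()]
#'   or [read_abundance_csv()].
#' @param breakpoint_day Breakpoint in days, `NULL` to grid-search, or `NA`
#'   for a single-segment fit.
#' @param per_replicate If `TRUE` (default), fit each replicate series
#'   separately and report one row per replicate and segment; otherwise fit
#'   the replicate-mean log ratios.
#' @param genes Genes to fit (default dsRed and gfp).
#' @return A data frame of decay-fit rows with treatment/gene/replicate
#'   identifiers, plus a `d_value` summary attribute (mean and sd of
#'   per-replicate D-values per treatment x gene x segment).
#' @export
fit_decay_table <- function(abundance, breakpoint_day = 15,
                            per_replicate = TRUE,
                            genes = c("dsRed", "gfp")) {
  rows <- list()
  for (tr in unique(abundance$treatment)) {
    for (g in genes) {
      sub <- abundance[abundance$treatment == tr & abundance$gene == g, ]
      if (nrow(sub) == 0L) next
      fit_series <- function(days, lr, rep_id) {
        ok <- is.finite(lr)
        f <- if (length(breakpoint_day) == 1L && is.na(breakpoint_day)) {
          fit_linear_decay(days[ok], lr[ok])
        } else {
          fit_biphasic(days[ok], lr[ok], breakpoint_day)
        }
        f$treatment <- tr; f$gene <- g; f$replicate <- rep_id
        f
      }
      if (per_replicate) {
        for (r in sort(unique(sub$replicate))) {
          s <- sub[sub$replicate == r, ]
          s <- s[order(s$day), ]
          c0 <- s$copies_per_g_dw[s$day == 0]
          if (length(c0) != 1L || !is.finite(c0) || c0 <= 0) next
          pos <- is.finite(s$copies_per_g_dw) & s$copies_per_g_dw > 0
          lr <- rep(NA_real_, nrow(s))
          lr[pos] <- log_ratio(s$copies_per_g_dw[pos], c0)
          rows[[length(rows) + 1L]] <- fit_series(s$day, lr, r)
        }
      } else {
        agg <- stats::aggregate(copies_per_g_dw ~ day, data = sub,
                                FUN = mean, na.action = stats::na.omit)
        agg <- agg[order(agg$day), ]
        c0 <- agg$copies_per_g_dw[agg$day == 0]
        pos <- agg$copies_per_g_dw > 0
        lr <- rep(NA_real_, nrow(agg))
        lr[pos] <- log_ratio(agg$copies_per_g_dw[pos], c0)
        rows[[length(rows) + 1L]] <- fit_series(agg$day, lr, NA_integer_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  finite_d <- out[is.finite(out$d_value), ]
  summ <- stats::aggregate(d_value ~ treatment + gene + segment,
                           data = finite_d, FUN = mean)
  names(summ)[names(summ) == "d_value"] <- "d_value_mean"
  summ$d_value_sd <- stats::aggregate(d_value ~ treatment + gene + segment,
                                      data = finite_d, FUN = stats::sd)$d_value
  attr(out, "d_value_summary") <- summ
  out
}
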