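## Reason-for-absence breakdowns, survival and retention rates, and median
## survival time.
##
## Denominators follow the cohort-accounting conventions of post-campaign
## durability monitoring:
##   * "surveyed at time x" means nets whose status at that round is known
##     after cleaning (UNSURVEYED cells excluded; cells filled by the
##     monotone rules count as known);
##   * the survival rate (present-and-serviceable nets) excludes the
##     give-away family (given away / stolen / exchanged) from the
##     denominator, since those nets' ultimate fate is unknown;
##   * the retention rate (present nets) excludes the discard family
##     (damaged-and-discarded / repurposed) from the denominator;
##   * UNKNOWN cells (ambiguous NOT_FOUND-before-DISCARDED) are excluded
##     from both rates — whether the net was still present at that round is
##     exactly what is not known; the Bayesian model, not the raw rates,
##     resolves them.
## Confidence intervals are 95% Wilson score intervals, which remain sensible
## at the small late-round denominators a shrinking cohort produces.

## first recorded loss cause per net (cause attached to the first terminal
## observation cell)
first_cause <- function(m) {
  apply(m$reason, 1, function(r) {
    w <- which(!is.na(r)); if (length(w)) r[w[1]] else NA_character_
  })
}

#' Per-round cohort accounting
#'
#' Counts nets present, absent (DISCARDED or NOT_FOUND), ambiguous (UNKNOWN)
#' and surveyed at a round of a cleaned matrix. Surveyed = present + absent +
#' ambiguous; UNSURVEYED cells are outside the round's denominator.
#'
#' @param m A cleaned `cohort_matrix`.
#' @param round Round in months (one of `m$rounds`).
#' @return One-row data frame with columns `round_months`, `n_present`,
#'   `n_absent`, `n_unknown`, `n_surveyed`.
#' @export
round_accounting <- function(m, round) {
  st <- status_at(m, round)
  n_present <- sum(st == "PRESENT")
  n_absent <- sum(st %in% c("DISCARDED", "NOT_FOUND"))
  n_unknown <- sum(st == "UNKNOWN")
  data.frame(round_months = round, n_present = n_present, n_absent = n_absent,
             n_unknown = n_unknown,
             n_surveyed = n_present + n_absent + n_unknown)
}

status_at <- function(m, round) {
  ci <- match(round, m$rounds)
  if (is.na(ci)) stop("round ", round, " not in matrix rounds")
  m$status[, ci]
}

#' Reasons for net absence at a round
#'
#' Tabulates nets absent at a round by first-recorded attrition cause, with
#' percentages of the absent total (rounded to 2 decimals in the printed
#' table; the returned values are exact). Absent nets with no recorded cause
#' (e.g. an unlocatable net never seen again) are reported in the
#' `n_unattributed` attribute and excluded from the cause total.
#'
#' @inheritParams round_accounting
#' @return Data frame with one row per cause: `round_months`, `cause`,
#'   `count`, `percent`; attributes `total_absent` and `n_unattributed`.
#'   With zero attributable absences the percentages are NA.
#' @examples
#' # Breakdown of 81 absent nets
#' counts <- c(given_away = 42, stolen = 8, exchanged = 20,
#'             damaged_discarded = 10, repurposed = 1)
#' @export
reason_breakdown <- function(m, round) {
  st <- status_at(m, round)
  absent <- st %in% c("DISCARDED", "NOT_FOUND")
  cause <- first_cause(m)[absent]
  counts <- table(factor(cause, levels = CAUSE_LEVELS))
  total <- sum(counts)
  pct <- if (total > 0) 100 * as.numeric(counts) / total else rep(NA_real_, length(counts))
  out <- data.frame(round_months = round,
                    cause = CAUSE_LEVELS,
                    count = as.integer(counts),
                    percent = pct,
                    stringsAsFactors = FALSE)
  attr(out, "total_absent") <- total
  attr(out, "n_unattributed") <- sum(absent) - total
  out
}

wilson_ci <- function(x, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  ## suppress the small-sample chi-squared warning: only the Wilson score
  ## interval is used, not the test itself
  as.numeric(suppressWarnings(
    stats::prop.test(x, n, conf.level = level, correct = FALSE))$conf.int)
}

rate_estimate <- function(round, kind, num, den, level = 0.95) {
  if (den == 0) {
    out <- data.frame(round_months = round, kind = kind, numerator = num,
                      denominator = den, proportion = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  ci <- 100 * wilson_ci(num, den, level)
  data.frame(round_months = round, kind = kind, numerator = num,
             denominator = den, proportion = 100 * num / den,
             ci_low = ci[1], ci_high = ci[2])
}

#' Survival and retention rates
#'
#' `survival_rate()` is the proportion of nets present *and serviceable*
#' (pHI <= 642) among nets surveyed at the round, excluding give-away-family
#' losses (given away / stolen / exchanged) from the denominator: it tracks
#' loss to physical wear. Present nets without a pHI measurement (cells
#' filled by backfilling, or missing hole counts) are treated as serviceable,
#' since their presence was established but their damage was not observed.
#' `retention_rate()` is the proportion of nets present among surveyed nets,
#' excluding discard-family losses (damaged-and-discarded / repurposed) from
#' the denominator: it tracks whether households keep their nets. Both carry
#' two-sided Wilson 95% confidence intervals.
#'
#' @param m A cleaned `cohort_matrix`.
#' @param phi Data frame as returned by [phi_table()] (columns `net_id`,
#'   `round_months`, `phi`); only needed for `survival_rate()`.
#' @param round Round in months.
#' @param level Confidence level (default 0.95).
#' @return One-row data frame of class rate estimate: `round_months`, `kind`,
#'   `numerator`, `denominator`, `proportion` (percent), `ci_low`, `ci_high`.
#'   A zero denominator yields NA proportions and an `undefined` attribute.
#' @export
survival_rate <- function(m, phi, round, level = 0.95) {
  st <- status_at(m, round)
  present <- st == "PRESENT"
  ## serviceability of present nets; unmeasured => serviceable
  pv <- phi[phi$round_months == round, , drop = FALSE]
  phi_vec <- pv$phi[match(rownames(m$status), pv$net_id)]
  serviceable <- is.na(phi_vec) | phi_vec <= PHI_SERVICEABLE_MAX
  num <- sum(present & serviceable)
  den <- sum(present) + sum(st == "DISCARDED")
  rate_estimate(round, "SURVIVAL", num, den, level)
}

#' @rdname survival_rate
#' @export
retention_rate <- function(m, round, level = 0.95) {
  st <- status_at(m, round)
  num <- sum(st == "PRESENT")
  den <- num + sum(st == "NOT_FOUND")
  rate_estimate(round, "RETENTION", num, den, level)
}

#' Rate tables by brand, zone or overall
#'
#' Computes survival and retention rates for every round, optionally split
#' by roster brand or zone.
#'
#' @inheritParams survival_rate
#' @param by `"overall"`, `"brand"` or `"zone"`.
#' @return Data frame with one row per round (x group) per rate kind, with a
#'   `group` column.
#' @export
rate_table <- function(m, phi, by = c("overall", "brand", "zone"), level = 0.95) {
  by <- match.arg(by)
  groups <- switch(by,
                   overall = list(overall = rep(TRUE, nrow(m$status))),
                   brand = split_index(m$roster$brand),
                   zone = split_index(m$roster$zone))
  out <- list()
  for (g in names(groups)) {
    sub <- subset_matrix(m, groups[[g]])
    for (r in m$rounds) {
      sr <- survival_rate(sub, phi, r, level)
      rr <- retention_rate(sub, r, level)
      sr$group <- g; rr$group <- g
      out[[length(out) + 1L]] <- rbind(sr, rr)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("group", setdiff(names(res), "group"))]
}

split_index <- function(f) {
  lapply(stats::setNames(sort(unique(f)), sort(unique(f))), function(v) f == v)
}

subset_matrix <- function(m, keep) {
  new_cohort_matrix(m$status[keep, , drop = FALSE],
                    m$reason[keep, , drop = FALSE],
                    m$filled[keep, , drop = FALSE],
                    m$rounds, m$roster[keep, , drop = FALSE])
}

#' Median survival time by linear interpolation
#'
#' Interpolates the time at which a survival or retention proportion crosses
#' 50%: \deqn{T_m = t_1 + (t_2 - t_1)(p_1 - 50)/(p_1 - p_2)} with `t1`, `t2`
#' in years and `p1`, `p2` in percent. The confidence interval applies the
#' same formula to the lower limits of `p1` and `p2`, and to the upper
#' limits, respectively. Two caveats are flagged rather than hidden:
#' projection towards the median is questionable when the first time point
#' exceeds 85% (`projection_warning`), and a crossing outside `[t1, t2]` is
#' an extrapolation of the linear segment (`extrapolated`).
#'
#' @param t1,t2 Times in years of the two survey points (t1 < t2).
#' @param p1,p2 Survival or retention percentages at `t1` and `t2`; must
#'   differ.
#' @param ci1,ci2 Optional length-2 vectors `(low, high)` of percent CI
#'   bounds at `t1` and `t2`.
#' @return Object of class `median_survival_time`: list with `tm`, `ci_low`,
#'   `ci_high`, the inputs, and logical flags `projection_warning` and
#'   `extrapolated`.
#' @examples
#' median_survival_time(1, 2, 75, 25)   # crosses 50% at 1.5 years
#' @export
median_survival_time <- function(t1, t2, p1, p2, ci1 = NULL, ci2 = NULL) {
  if (t2 <= t1) stop("t2 must exceed t1")
  if (isTRUE(all.equal(p1, p2))) stop("degenerate slope: p1 equals p2")
  interp <- function(a, b) t1 + (t2 - t1) * (a - 50) / (a - b)
  tm <- interp(p1, p2)
  ci_low <- ci_high <- NA_real_
  if (!is.null(ci1) && !is.null(ci2)) {
    stopifnot(length(ci1) == 2, length(ci2) == 2)
    bounds <- c(interp(ci1[1], ci2[1]), interp(ci1[2], ci2[2]))
    ci_low <- min(bounds); ci_high <- max(bounds)
  }
  projection_warning <- p1 > 85
  if (projection_warning)
    warning("first time point above 85%: projection toward the median is unreliable")
  structure(list(t1 = t1, t2 = t2, p1 = p1, p2 = p2,
                 tm = tm, ci_low = ci_low, ci_high = ci_high,
                 projection_warning = projection_warning,
                 extrapolated = tm < t1 || tm > t2),
            class = "median_survival_time")
}

#' @export
print.median_survival_time <- function(x, ...) {
  cat(sprintf("Median survival time: %.2f years", x$tm))
  if (!is.na(x$ci_low))
    cat(sprintf(" (95%% CI %.2f-%.2f)", x$ci_low, x$ci_high))
  cat("\n")
  if (x$projection_warning)
    cat("  note: first time point > 85%, projection unreliable\n")
  if (x$extrapolated)
    cat("  note: crossing lies outside [t1, t2] (linear extrapolation)\n")
  invisible(x)
}

#' Median survival/retention time table per brand
#'
#' Applies [median_survival_time()] to the 12- and 24-month rates of each
#' brand (t1 = 1 year, t2 = 2 years), for both the survival and the
#' retention definition.
#'
#' @inheritParams rate_table
#' @param t1_months,t2_months Rounds (months) used as the two interpolation
#'   points; default 12 and 24.
#' @return Data frame: `group`, `kind`, `tm_years`, `ci_low`, `ci_high`,
#'   `projection_warning`, `extrapolated` (NA rows where the slope is
#'   degenerate or a rate undefined).
#' @export
median_survival_table <- function(m, phi, by = "brand",
                                  t1_months = 12, t2_months = 24) {
  rt <- rate_table(m, phi, by = by)
  out <- list()
  for (g in unique(rt$group)) for (kind in c("SURVIVAL", "RETENTION")) {
    r1 <- rt[rt$group == g & rt$kind == kind & rt$round_months == t1_months, ]
    r2 <- rt[rt$group == g & rt$kind == kind & rt$round_months == t2_months, ]
    row <- data.frame(group = g, kind = kind, tm_years = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      projection_warning = NA, extrapolated = NA)
    ok <- nrow(r1) == 1 && nrow(r2) == 1 && !is.na(r1$proportion) &&
      !is.na(r2$proportion) && !isTRUE(all.equal(r1$proportion, r2$proportion))
    if (ok) {
      tm <- suppressWarnings(median_survival_time(
        t1_months / 12, t2_months / 12, r1$proportion, r2$proportion,
        ci1 = c(r1$ci_low, r1$ci_high), ci2 = c(r2$ci_low, r2$ci_high)))
      row$tm_years <- tm$tm; row$ci_low <- tm$ci_low; row$ci_high <- tm$ci_high
      row$projection_warning <- tm$projection_warning
      row$extrapolated <- tm$extrapolated
    }
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
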