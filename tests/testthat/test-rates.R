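# Reason breakdowns, survival/retention rates and median survival time.

test_that("reason breakdown reproduces percentages from absolute counts", {
  counts <- c(given_away = 42, stolen = 8, exchanged = 20,
              damaged_discarded = 10, repurposed = 1)
  m <- one_round_absences(counts)
  bd <- reason_breakdown(m, 6)
  expect_equal(attr(bd, "total_absent"), 81)
  expect_equal(round(bd$percent[bd$cause == "given_away"], 2), 51.85)
  expect_equal(round(bd$percent[bd$cause == "exchanged"], 2), 24.69)
  expect_equal(sum(bd$percent), 100)
  # a single cause gets 100%
  m1 <- one_round_absences(c(given_away = 0, stolen = 7, exchanged = 0,
                             damaged_discarded = 0, repurposed = 0))
  bd1 <- reason_breakdown(m1, 6)
  expect_equal(bd1$percent[bd1$cause == "stolen"], 100)
  # zero absent nets: zero total, NA percentages
  m0 <- one_round_absences(setNames(rep(0, 5), names(counts)), n_present = 4)
  bd0 <- reason_breakdown(m0, 6)
  expect_equal(attr(bd0, "total_absent"), 0)
  expect_true(all(is.na(bd0$percent)))
})

test_that("retention rate uses the paper-style denominator exclusions", {
  # 100 surveyed, 20 given away, 0 discarded: 80/100
  m <- one_round_absences(c(given_away = 20, stolen = 0, exchanged = 0,
                            damaged_discarded = 0, repurposed = 0),
                          n_present = 80)
  rr <- retention_rate(m, 6)
  expect_equal(rr$numerator, 80)
  expect_equal(rr$denominator, 100)
  expect_equal(rr$proportion, 80)
  expect_true(rr$ci_low <= 80 && 80 <= rr$ci_high)
  # 100 surveyed, 20 discarded: discard family excluded, 80/80 = 100%
  m2 <- one_round_absences(c(given_away = 0, stolen = 0, exchanged = 0,
                             damaged_discarded = 20, repurposed = 0),
                           n_present = 80)
  rr2 <- retention_rate(m2, 6)
  expect_equal(rr2$denominator, 80)
  expect_equal(rr2$proportion, 100)
})

test_that("survival rate counts present-and-serviceable over the wear denominator", {
  # half the present nets torn, no give-away losses: 50%
  roster <- make_roster(40)
  obs <- data.frame(net_id = roster$net_id, round_months = 6,
                    status = "PRESENT", reason = NA,
                    holes1 = 0, holes2 = 0, holes3 = 0,
                    holes4 = rep(c(0, 2), 20))  # 2 size-4 holes: pHI 1152
  m <- build_status_matrix(roster, obs, 6)
  sr <- survival_rate(m, phi_table(obs), 6)
  expect_equal(sr$numerator, 20)
  expect_equal(sr$denominator, 40)
  expect_equal(sr$proportion, 50)
  # all present and serviceable: 100% with CI reaching 100
  obs2 <- obs; obs2$holes4 <- 0
  sr2 <- survival_rate(build_status_matrix(roster, obs2, 6),
                       phi_table(obs2), 6)
  expect_equal(sr2$proportion, 100)
  expect_equal(sr2$ci_high, 100)
})

test_that("give-away losses are excluded from the survival denominator", {
  counts <- c(given_away = 30, stolen = 0, exchanged = 0,
              damaged_discarded = 10, repurposed = 0)
  m <- one_round_absences(counts, n_present = 60)
  phi <- data.frame(net_id = character(0), round_months = numeric(0),
                    phi = numeric(0))
  sr <- survival_rate(m, phi, 6)
  # denominator: 60 present + 10 discarded; the 30 given away are excluded
  expect_equal(sr$denominator, 70)
  expect_equal(sr$numerator, 60)
  # with no losses of either family, survival and retention coincide
  m0 <- one_round_absences(setNames(rep(0, 5), names(counts)), n_present = 50)
  expect_equal(survival_rate(m0, phi, 6)$proportion,
               retention_rate(m0, 6)$proportion)
})

test_that("zero denominators yield the undefined-rate sentinel", {
  m <- one_round_absences(c(given_away = 5, stolen = 0, exchanged = 0,
                            damaged_discarded = 0, repurposed = 0))
  phi <- data.frame(net_id = character(0), round_months = numeric(0),
                    phi = numeric(0))
  sr <- survival_rate(m, phi, 6)
  expect_true(is.na(sr$proportion))
  expect_true(isTRUE(attr(sr, "undefined")))
})

test_that("per-round accounting satisfies present + absent = surveyed", {
  co <- simulate_cohort(cohort_config(n_households = 300, seed = 19))
  m <- clean_status_matrix(build_status_matrix(co$roster, co$observations,
                                               rounds4))
  for (r in rounds4) {
    acc <- round_accounting(m, r)
    expect_equal(acc$n_present + acc$n_absent + acc$n_unknown, acc$n_surveyed)
  }
})

test_that("survival rate tracks configured cumulative survival on clean cohorts", {
  s <- c(0.95, 0.9, 0.85, 0.8)
  # all losses are discard-family (kept in the denominator), no holes, no noise
  cw <- matrix(0, 4, 5, dimnames = list(NULL, attrition_causes()))
  cw[, "damaged_discarded"] <- 1
  cfg <- quick_config(n_households = 4000,
                      brand_survival = matrix(s, 1, dimnames = list("A", NULL)),
                      household_sd = 0, zone_log_odds = 0,
                      cause_weights = cw, hole_rates = rep(0, 4),
                      missingness = rep(0, 4), misreport_notfound = 0,
                      present_notfound = 0, seed = 27)
  co <- simulate_cohort(cfg)
  m <- clean_status_matrix(build_status_matrix(co$roster, co$observations,
                                               rounds4))
  phi <- phi_table(co$observations)
  for (r in seq_along(rounds4)) {
    p <- 100 * prod(s[seq_len(r)])
    sr <- survival_rate(m, phi, rounds4[r])
    expect_lt(abs(sr$proportion - p),
              3.5 * 100 * sqrt(p / 100 * (1 - p / 100) / sr$denominator))
  }
})

test_that("median survival time follows the interpolation formula", {
  expect_equal(median_survival_time(1, 2, 50, 20)$tm, 1)
  expect_equal(median_survival_time(1, 2, 75, 25)$tm, 1.5)
  expect_equal(suppressWarnings(median_survival_time(1, 2, 100, 0))$tm, 1.5)
  expect_error(median_survival_time(1, 2, 60, 60), "degenerate")
  # CI pairs lower-with-lower, upper-with-upper
  tm <- median_survival_time(1, 2, 75, 25, ci1 = c(65, 85), ci2 = c(15, 35))
  expect_equal(tm$ci_low, 1 + (65 - 50) / (65 - 15))
  expect_equal(tm$ci_high, 1 + (85 - 50) / (85 - 35))
})

test_that("projection and extrapolation flags fire per the 85% rule", {
  expect_warning(tm <- median_survival_time(1, 2, 90, 40), "85")
  expect_true(tm$projection_warning)
  tm2 <- median_survival_time(1, 2, 80, 70)  # crosses after t2
  expect_true(tm2$extrapolated)
  expect_gt(tm2$tm, 2)
  expect_false(tm2$projection_warning)
})

test_that("median survival time is shift-invariant in time", {
  a <- median_survival_time(1, 2, 70, 30)
  b <- median_survival_time(1.5, 2.5, 70, 30)
  expect_equal(b$tm, a$tm + 0.5)
})

test_that("rate and median tables have one row per group, round and kind", {
  co <- simulate_cohort(cohort_config(n_households = 250, seed = 23))
  m <- clean_status_matrix(build_status_matrix(co$roster, co$observations,
                                               rounds4))
  phi <- phi_table(co$observations)
  rt <- rate_table(m, phi, by = "brand")
  nb <- length(unique(co$roster$brand))
  expect_equal(nrow(rt), nb * length(rounds4) * 2)
  tmt <- median_survival_table(m, phi, by = "brand")
  expect_equal(nrow(tmt), nb * 2)
})
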