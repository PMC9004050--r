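# The Gibbs sampler and its data augmentation.

test_that("failure-interval full conditional matches path enumeration", {
  # oracle: enumerate the monotone paths explicitly
  enum <- function(p) {
    w <- sapply(seq_along(p), function(j) prod(p[seq_len(j - 1)]) * (1 - p[j]))
    w / sum(w)
  }
  for (p in list(c(0.5, 0.5), c(0.9, 0.2), c(0.3, 0.3, 0.3), c(0.7)))
    expect_equal(failure_interval_probs(p), enum(p))
  # survival 0.5 then 0: both paths equally likely
  expect_equal(failure_interval_probs(c(0.5, 0)), c(0.5, 0.5))
  # near-certain survival into the ambiguous round: imputed present w.p. ~ 1
  pr <- failure_interval_probs(c(0.999, 0.5))
  expect_lt(pr[1], 0.01)
  # degenerate all-survive window resolves to earliest failure
  expect_equal(failure_interval_probs(c(1, 1)), c(1, 0))
})

test_that("with complete data and no random effects the Gibbs posterior matches the Beta closed form", {
  cfg <- quick_config(
    n_households = 300,
    brand_survival = matrix(c(0.9, 0.8, 0.9, 0.7, 0.85, 0.6, 0.8, 0.75), 2,
                            byrow = TRUE, dimnames = list(c("A", "B"), NULL)),
    household_sd = 0, zone_log_odds = 0, missingness = rep(0, 4),
    misreport_notfound = 0, present_notfound = 0, seed = 31)
  co <- simulate_cohort(cfg)
  m <- clean_status_matrix(build_status_matrix(co$roster, co$observations,
                                               rounds4))
  expect_equal(sum(m$status == "UNKNOWN"), 0)
  fit <- fit_net_survival(m, variant = "brand", household_re = FALSE,
                          chains = 2, iter = 1500, burnin = 500, seed = 41)
  expect_true(fit$conjugate)
  counts <- count_interval_survival(m)
  draws <- fit$draws$s
  for (i in seq_len(nrow(counts))) {
    cn <- sprintf("s[%s,%d]", counts$brand[i], counts$interval[i])
    a <- counts$surv[i] + 1; b <- counts$at_risk[i] - counts$surv[i] + 1
    closed_form <- a / (a + b)
    mcse <- sd(draws[, cn]) / sqrt(nrow(draws))
    expect_lt(abs(mean(draws[, cn]) - closed_form), 4 * mcse)
  }
})

test_that("an all-present cohort concentrates cumulative survival near 1", {
  cfg <- quick_config(
    n_households = 150,
    brand_survival = matrix(1, 1, 4, dimnames = list("A", NULL)),
    household_sd = 0, zone_log_odds = 0, missingness = rep(0, 4),
    misreport_notfound = 0, present_notfound = 0, seed = 2)
  co <- simulate_cohort(cfg)
  m <- clean_status_matrix(build_status_matrix(co$roster, co$observations,
                                               rounds4))
  fit <- fit_net_survival(m, variant = "brand", household_re = FALSE,
                          chains = 2, iter = 1000, burnin = 500, seed = 1)
  ps <- posterior_survival(fit)
  expect_true(all(ps$mean > 0.95))
})

test_that("imputed ambiguous statuses follow the full conditional given the data", {
  # complete nets pin the interval survivals near 0.5 for intervals 2 and 3;
  # window nets PRESENT -> NOT_FOUND -> DISCARDED are then imputed present at
  # the ambiguous round with probability p2 (1 - p3) / ((1 - p2) + p2 (1 - p3))
  full <- matrix(rep(c("PRESENT", "PRESENT", "PRESENT", "PRESENT"), 40),
                 ncol = 4, byrow = TRUE)
  die2 <- matrix(rep(c("PRESENT", "DISCARDED", "DISCARDED", "DISCARDED"), 80),
                 ncol = 4, byrow = TRUE)
  die3 <- matrix(rep(c("PRESENT", "PRESENT", "DISCARDED", "DISCARDED"), 40),
                 ncol = 4, byrow = TRUE)
  win <- matrix(rep(c("PRESENT", "NOT_FOUND", "DISCARDED", "DISCARDED"), 30),
                ncol = 4, byrow = TRUE)
  traj <- rbind(full, die2, die3, win)
  m <- clean_status_matrix(matrix_from_traj(traj))
  expect_equal(sum(m$status == "UNKNOWN"), 30)
  fit <- fit_net_survival(m, variant = "brand", household_re = FALSE,
                          chains = 2, iter = 2000, burnin = 1000,
                          keep_latent = TRUE, seed = 77)
  tr <- imputed_trajectories(fit)
  # imputed presence share at the ambiguous (second) round of each window
  amb <- tr$window_round == 2
  share <- mean(tr$present[, amb])
  p2 <- mean(fit$draws$s[, "s[A,2]"]); p3 <- mean(fit$draws$s[, "s[A,3]"])
  expected <- p2 * (1 - p3) / ((1 - p2) + p2 * (1 - p3))
  expect_lt(abs(share - expected), 0.05)
})

test_that("imputed trajectories are monotone in every retained iteration", {
  co <- simulate_cohort(cohort_config(n_households = 300, seed = 55,
                                      missingness = c(0, 0.2, 0.2, 0.2),
                                      misreport_notfound = 0.5))
  m <- clean_status_matrix(build_status_matrix(co$roster, co$observations,
                                               rounds4))
  expect_gt(sum(m$status == "UNKNOWN"), 0)
  fit <- fit_net_survival(m, variant = "brand", chains = 2, iter = 600,
                          burnin = 300, keep_latent = TRUE, seed = 5)
  tr <- imputed_trajectories(fit)
  for (g in unique(tr$window_net)) {
    cols <- which(tr$window_net == g)
    if (length(cols) < 2) next
    diffs <- tr$present[, cols[-1], drop = FALSE] -
      tr$present[, cols[-length(cols)], drop = FALSE]
    expect_true(all(diffs <= 0))  # never absent -> present within a net
  }
})

test_that("zone effect summarises draws correctly and guards the variant", {
  z <- odds_ratio_summary(rep(0, 50))
  expect_equal(unname(z$or["mean"]), 1)
  expect_equal(z$or_of_mean, 1)
  # exponentiate-then-summarise, not the reverse
  set.seed(1)
  b <- rnorm(4000, 0.9, 0.2)
  z2 <- odds_ratio_summary(b)
  expect_equal(unname(z2$or["mean"]), mean(exp(b)))
  expect_equal(unname(z2$or["lower"]), unname(quantile(exp(b), 0.025)))
  expect_gt(z2$or["mean"], z2$or_of_mean)  # Jensen
  co <- simulate_cohort(quick_config(n_households = 60, seed = 3))
  m <- clean_status_matrix(build_status_matrix(co$roster, co$observations,
                                               rounds4))
  fit <- fit_net_survival(m, variant = "brand", household_re = FALSE,
                          chains = 2, iter = 300, burnin = 150, seed = 1)
  expect_error(zone_effect(fit), "zone")
})

test_that("posterior summaries use equal-tailed empirical quantiles", {
  co <- simulate_cohort(quick_config(n_households = 80, seed = 13))
  m <- clean_status_matrix(build_status_matrix(co$roster, co$observations,
                                               rounds4))
  fit <- fit_net_survival(m, variant = "brand", household_re = FALSE,
                          chains = 2, iter = 700, burnin = 200, seed = 9)
  sm <- summary(fit, level = 0.95)
  for (cn in colnames(fit$draws$s)) {
    row <- sm[sm$parameter == cn, ]
    expect_equal(row$mean, mean(fit$draws$s[, cn]))
    expect_equal(row$lower, unname(quantile(fit$draws$s[, cn], 0.025)))
    expect_equal(row$upper, unname(quantile(fit$draws$s[, cn], 0.975)))
  }
  expect_error(summary(fit, level = 1.2), "level")
  # cumulative survival is nonincreasing across rounds within each draw
  S <- llindur:::cumulative_survival_draws(fit)$ref
  expect_true(all(S[, 2:4] <= S[, 1:3] + 1e-12))
})

test_that("posterior summaries are invariant to net order", {
  co <- simulate_cohort(quick_config(n_households = 100, seed = 29,
                                     missingness = rep(0, 4),
                                     misreport_notfound = 0,
                                     present_notfound = 0))
  m <- clean_status_matrix(build_status_matrix(co$roster, co$observations,
                                               rounds4))
  perm <- sample(nrow(co$roster))
  m2 <- clean_status_matrix(build_status_matrix(
    co$roster[perm, ], co$observations, rounds4))
  f1 <- fit_net_survival(m, variant = "brand", household_re = FALSE,
                         chains = 2, iter = 400, burnin = 200, seed = 7)
  f2 <- fit_net_survival(m2, variant = "brand", household_re = FALSE,
                         chains = 2, iter = 400, burnin = 200, seed = 7)
  expect_equal(summary(f1), summary(f2))
})

test_that("brand-intervals without data fall back to the prior with a warning", {
  # brand B disappears at the first round: intervals 2-4 carry no information
  trajA <- matrix(rep(c("PRESENT", "PRESENT", "PRESENT", "PRESENT"), 20),
                  ncol = 4, byrow = TRUE)
  trajB <- matrix(rep(c("NOT_FOUND", NA, NA, NA), 20), ncol = 4, byrow = TRUE)
  roster <- make_roster(40, brand = rep(c("A", "B"), each = 20))
  m <- clean_status_matrix(matrix_from_traj(rbind(trajA, trajB),
                                            roster = roster))
  expect_warning(
    fit <- fit_net_survival(m, variant = "brand", household_re = FALSE,
                            chains = 2, iter = 400, burnin = 200, seed = 3),
    "prior")
  # Beta(1, 1) prior: mean near 0.5, wide interval
  sm <- summary(fit)
  row <- sm[sm$parameter == "s[B,3]", ]
  expect_gt(row$upper - row$lower, 0.8)
})
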