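# Fixture builders used across the test files. Everything is generated in
# code; no stored data.

rounds4 <- c(6, 12, 24, 36)

# roster of n nets, one per household unless hh is given
make_roster <- function(n, brand = "A", zone = "urban", hh = NULL) {
  data.frame(net_id = sprintf("N%04d", seq_len(n)),
             household_id = if (is.null(hh)) sprintf("H%04d", seq_len(n)) else hh,
             brand = rep_len(brand, n),
             zone = rep_len(zone, n),
             stringsAsFactors = FALSE)
}

# build a cohort_matrix from per-net raw trajectories given as a character
# matrix with entries in {PRESENT, DISCARDED, NOT_FOUND, NA}; NA = household
# not visited (no observation row). reasons: optional matrix aligned with
# traj, giving the cause recorded at a cell.
matrix_from_traj <- function(traj, reasons = NULL, roster = NULL,
                             rounds = rounds4) {
  traj <- rbind(traj)
  n <- nrow(traj)
  if (is.null(roster)) roster <- make_roster(n)
  obs <- list()
  for (i in seq_len(n)) for (j in seq_along(rounds)) {
    if (is.na(traj[i, j])) next
    obs[[length(obs) + 1L]] <- data.frame(
      net_id = roster$net_id[i], round_months = rounds[j],
      status = traj[i, j],
      reason = if (is.null(reasons)) NA_character_ else reasons[i, j],
      stringsAsFactors = FALSE)
  }
  build_status_matrix(roster, do.call(rbind, obs), rounds)
}

# a config for quick simulations: one brand unless stated
quick_config <- function(n_households = 200, brand_survival = NULL, ...) {
  if (is.null(brand_survival))
    brand_survival <- matrix(c(0.95, 0.9, 0.85, 0.8), 1,
                             dimnames = list("A", NULL))
  cohort_config(n_households = n_households, brand_survival = brand_survival,
                nets_per_household = 1, ...)
}

# a single-round matrix with the given per-cause absent counts, n_present
# present nets and optionally extra unsurveyed roster nets
one_round_absences <- function(counts, n_present = 0, round = 6,
                               n_unsurveyed = 0) {
  statuses <- c(given_away = "NOT_FOUND", stolen = "NOT_FOUND",
                exchanged = "NOT_FOUND", damaged_discarded = "DISCARDED",
                repurposed = "DISCARDED")
  n <- sum(counts) + n_present + n_unsurveyed
  roster <- make_roster(n)
  cause <- rep(names(counts), counts)
  k <- sum(counts) + n_present
  obs <- data.frame(net_id = roster$net_id[seq_len(k)],
                    round_months = round,
                    status = c(unname(statuses[cause]), rep("PRESENT", n_present)),
                    reason = c(cause, rep(NA, n_present)),
                    stringsAsFactors = FALSE)
  build_status_matrix(roster, obs, rounds = round)
}

# independent at-risk/survivor counts per (brand, interval) straight from a
# cleaned status matrix with complete observation (no UNSURVEYED, no UNKNOWN)
count_interval_survival <- function(m) {
  st <- m$status
  K <- ncol(st)
  brands <- sort(unique(m$roster$brand))
  out <- list()
  for (b in brands) {
    rows <- m$roster$brand == b
    for (k in seq_len(K)) {
      at_risk <- if (k == 1) sum(rows) else sum(rows & st[, k - 1] == "PRESENT")
      surv <- sum(rows & st[, k] == "PRESENT")
      out[[length(out) + 1L]] <- data.frame(brand = b, interval = k,
                                            at_risk = at_risk, surv = surv)
    }
  }
  do.call(rbind, out)
}
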