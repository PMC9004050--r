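## End-to-end orchestration: simulate (or load) -> validate -> clean -> pHI
## -> rates -> Bayesian fits -> consolidated report bundle.

#' Validate roster and observation files
#'
#' Schema checks on the delimited cohort inputs: required columns, status
#' vocabulary, nonnegative integer hole counts, duplicate roster keys,
#' duplicate (net, round) cells and orphan net IDs. Errors are collected,
#' not thrown.
#'
#' @param roster_path,observations_path Paths to the CSV files.
#' @return Data frame with columns `file`, `row`, `problem`; zero rows if
#'   the files are well-formed.
#' @export
validate_cohort_files <- function(roster_path, observations_path) {
  problems <- list()
  note <- function(file, row, problem)
    problems[[length(problems) + 1L]] <<- data.frame(
      file = file, row = row, problem = problem, stringsAsFactors = FALSE)
  roster <- utils::read.csv(roster_path, colClasses = "character")
  obs <- utils::read.csv(observations_path, stringsAsFactors = FALSE)
  for (col in c("net_id", "household_id", "brand", "zone"))
    if (!col %in% names(roster)) note("roster", NA, paste("missing column", col))
  for (col in c("net_id", "round_months", "status"))
    if (!col %in% names(obs)) note("observations", NA, paste("missing column", col))
  if (length(problems)) return(do.call(rbind, problems))

  dup <- which(duplicated(roster$net_id))
  for (r in dup) note("roster", r, paste("duplicated net_id", roster$net_id[r]))
  if ("zone" %in% names(roster)) {
    bad <- which(!roster$zone %in% c("rural", "urban"))
    for (r in bad) note("roster", r, paste("invalid zone", roster$zone[r]))
  }
  bad <- which(!obs$status %in% c("PRESENT", "DISCARDED", "NOT_FOUND"))
  for (r in bad) note("observations", r, paste("invalid status", obs$status[r]))
  if ("reason" %in% names(obs)) {
    bad <- which(!is.na(obs$reason) & obs$reason != "" &
                   !obs$reason %in% CAUSE_LEVELS)
    for (r in bad) note("observations", r, paste("invalid reason", obs$reason[r]))
  }
  orphan <- which(!obs$net_id %in% roster$net_id)
  for (r in orphan) note("observations", r, paste("net_id not in roster", obs$net_id[r]))
  key <- paste(obs$net_id, obs$round_months)
  dup <- which(duplicated(key))
  for (r in dup) note("observations", r, paste("duplicate (net, round)", key[r]))
  for (h in paste0("holes", 1:4)) {
    if (!h %in% names(obs)) next
    v <- obs[[h]]
    bad <- which(!is.na(v) & (v < 0 | v != round(as.numeric(v))))
    for (r in bad) note("observations", r, paste("invalid", h, v[r]))
  }
  if (!length(problems))
    return(data.frame(file = character(0), row = integer(0),
                      problem = character(0)))
  out <- do.call(rbind, problems)
  rownames(out) <- NULL
  out
}

#' Run the full durability analysis pipeline
#'
#' Orchestrates the whole chain on either a freshly simulated cohort or
#' cohort files read from disk: cleaning into the monotone status matrix,
#' pHI scoring, per-round accounting and reason breakdowns, survival and
#' retention rate tables (overall, per brand, per zone), median survival
#' times, and the Bayesian model fits (per-brand and zone-covariate
#' variants). Deterministic given the seed.
#'
#' @param config A [cohort_config()] to simulate from, or NULL when reading
#'   files.
#' @param roster,observations Data frames (alternative to `config`).
#' @param rounds Survey months (required when supplying data frames).
#' @param output_dir Optional directory; when given, every table plus a YAML
#'   run manifest (package version, configuration, input checksums) is
#'   written as delimited text.
#' @param chains,iter,burnin MCMC settings passed to [fit_net_survival()].
#' @param fit_variants Character subset of `c("brand", "zone")`.
#' @param seed Seed for the model fits (the simulation uses `config$seed`).
#' @return List of class `llin_report`: accounting, reason breakdowns (long
#'   and wide), rate tables, median survival table, fit summaries, zone
#'   effect, and the manifest.
#' @export
run_pipeline <- function(config = NULL, roster = NULL, observations = NULL,
                         rounds = NULL, output_dir = NULL,
                         chains = 2, iter = 2000, burnin = 1000,
                         fit_variants = c("brand", "zone"), seed = 1L) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "cohort_config"))
    cohort <- simulate_cohort(config)
    roster <- cohort$roster
    observations <- cohort$observations
    rounds <- config$rounds
  } else if (is.null(roster) || is.null(observations) || is.null(rounds)) {
    stop("supply either a cohort_config or roster + observations + rounds")
  }
  m <- clean_status_matrix(build_status_matrix(roster, observations, rounds))
  phi <- phi_table(observations)

  accounting <- do.call(rbind, lapply(rounds, function(r) round_accounting(m, r)))
  breakdown <- do.call(rbind, lapply(rounds, function(r) reason_breakdown(m, r)))
  breakdown_wide <- stats::reshape(
    breakdown, idvar = "cause", timevar = "round_months", direction = "wide")
  rates <- list(overall = rate_table(m, phi, "overall"),
                brand = rate_table(m, phi, "brand"),
                zone = rate_table(m, phi, "zone"))
  tm <- median_survival_table(m, phi, by = "brand")

  fits <- list(); summaries <- list(); zone_eff <- NULL
  for (v in fit_variants) {
    fits[[v]] <- fit_net_survival(m, variant = v, chains = chains,
                                  iter = iter, burnin = burnin, seed = seed)
    summaries[[v]] <- summary(fits[[v]])
  }
  if ("zone" %in% fit_variants) zone_eff <- zone_effect(fits[["zone"]])

  manifest <- list(package = "llindur",
                   version = as.character(utils::packageVersion("llindur")),
                   seed = seed,
                   rounds = rounds,
                   n_nets = nrow(roster),
                   n_observations = nrow(observations),
                   mcmc = list(chains = chains, iter = iter, burnin = burnin),
                   simulated = !is.null(config),
                   config = if (!is.null(config)) unclass_config(config))

  report <- structure(list(accounting = accounting,
                           reason_breakdown = breakdown,
                           reason_breakdown_wide = breakdown_wide,
                           rates = rates,
                           median_survival = tm,
                           fit_summaries = summaries,
                           fits = fits,
                           zone_effect = zone_eff,
                           matrix = m,
                           phi = phi,
                           manifest = manifest),
                      class = "llin_report")
  if (!is.null(output_dir)) write_report(report, output_dir,
                                         roster, observations)
  report
}

unclass_config <- function(config) {
  x <- unclass(config)
  x$brand_survival <- apply(x$brand_survival, 1, as.numeric, simplify = FALSE)
  x$cause_weights <- apply(x$cause_weights, 1, as.numeric, simplify = FALSE)
  x$hole_brand_multiplier <- as.list(x$hole_brand_multiplier)
  x
}

write_report <- function(report, output_dir, roster, observations) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name)
    utils::write.csv(x, file.path(output_dir, name), row.names = FALSE)
  wr(report$accounting, "accounting.csv")
  wr(report$reason_breakdown, "reason_breakdown.csv")
  wr(report$rates$overall, "rates_overall.csv")
  wr(report$rates$brand, "rates_brand.csv")
  wr(report$rates$zone, "rates_zone.csv")
  wr(report$median_survival, "median_survival.csv")
  for (v in names(report$fit_summaries))
    wr(report$fit_summaries[[v]], paste0("posterior_", v, ".csv"))
  write_status_matrix(report$matrix, file.path(output_dir, "cleaned_matrix.csv"))
  wr(roster, "roster.csv")
  wr(observations, "observations.csv")
  manifest <- report$manifest
  manifest$checksums <- as.list(tools::md5sum(
    file.path(output_dir, c("roster.csv", "observations.csv"))))
  names(manifest$checksums) <- c("roster.csv", "observations.csv")
  yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  invisible(output_dir)
}

#' @export
print.llin_report <- function(x, ...) {
  cat("LLIN durability report —", x$manifest$n_nets, "nets, rounds",
      paste(x$manifest$rounds, collapse = "/"), "months\n\n")
  cat("Cohort accounting:\n")
  print(x$accounting, row.names = FALSE)
  cat("\nOverall rates:\n")
  print(x$rates$overall[, c("kind", "round_months", "numerator", "denominator",
                            "proportion", "ci_low", "ci_high")],
        row.names = FALSE, digits = 4)
  if (!is.null(x$zone_effect)) {
    cat("\n"); print(x$zone_effect)
  }
  invisible(x)
}
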