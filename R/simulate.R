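## Synthetic LLIN cohort generator.
##
## Emulates a post-campaign durability cohort: households in rural/urban
## strata, one net brand per household (large households can hold several
## sampled nets of the same product), a latent discrete-time survival process
## on the round grid with brand-by-interval survival probabilities, a rural
## log-odds shift and a household random effect on the logit scale, competing
## attrition causes drawn at the failure round, Poisson hole accumulation in
## the four WHO size classes for surviving nets, and household-level
## missingness (a whole household unvisited at a round produces no
## observation rows). Reporting noise creates the raw NOT_FOUND-before-
## DISCARDED patterns that cleaning later marks UNKNOWN.

#' Default brand survival table
#'
#' Per-interval conditional survival probabilities (reference urban household,
#' random effect zero) for the eight product types of the default simulated
#' campaign. Values are chosen so that cumulative survival over the first
#' three intervals spans the realistic 50-90% range at 24 months.
#'
#' @return Numeric matrix, brands x intervals.
#' @export
default_brand_survival <- function() {
  s <- rbind(
    "Interceptor"    = c(0.99, 0.95, 0.933, 0.930),
    "PermaNet 2.0 C" = c(0.99, 0.95, 0.924, 0.915),
    "Life Net"       = c(0.99, 0.94, 0.920, 0.850),
    "PermaNet 2.0 R" = c(0.98, 0.90, 0.758, 0.850),
    "MAGNet"         = c(0.98, 0.88, 0.704, 0.850),
    "Netprotect"     = c(0.98, 0.87, 0.692, 0.850),
    "Olyset Net"     = c(0.98, 0.85, 0.669, 0.850),
    "Yorkool LN"     = c(0.97, 0.82, 0.644, 0.850))
  colnames(s) <- c("i1", "i2", "i3", "i4")
  s
}

## Default cause weights per round, {given_away, stolen, exchanged,
## damaged_discarded, repurposed}: early losses dominated by redistribution,
## later losses by damage and theft.
default_cause_weights <- function() {
  w <- rbind(c(42, 8, 20, 10, 1),
             c(118, 83, 10, 67, 8),
             c(143, 200, 33, 241, 13),
             c(6, 9, 2, 32, 0))
  colnames(w) <- CAUSE_LEVELS
  rownames(w) <- paste0("round", 1:4)
  w
}

#' Simulation configuration for a synthetic net cohort
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cohort()]. Defaults emulate a campaign cohort of roughly 2,200
#' nets across 8 brands and 2 zones observed at 6, 12, 24 and 36 months, with
#' heavy late-round household attrition.
#'
#' @param n_households Number of households.
#' @param nets_per_household Mean number of sampled nets per household
#'   (must be >= 1); realised counts are `1 + Poisson(mean - 1)`.
#' @param brand_survival Matrix (brands x intervals) of per-interval
#'   conditional survival probabilities in (0, 1] for the reference (urban,
#'   random effect zero) household. Row names are brand labels.
#' @param zone_mix Proportion of households in the rural stratum, in [0, 1].
#' @param zone_log_odds Log-odds shift of interval survival for rural
#'   households relative to urban ones.
#' @param household_sd Standard deviation (logit scale) of the household
#'   random effect; 0 disables clustering.
#' @param cause_weights Matrix (rounds x 5 causes) of nonnegative weights for
#'   the attrition cause drawn at the failure round; columns must be named as
#'   [attrition_causes()]. Each row must have positive sum.
#' @param hole_rates Per-year Poisson arrival rates for holes in the four
#'   size classes (length-4 vector).
#' @param hole_brand_multiplier Named multiplier per brand applied to
#'   `hole_rates` (fragile fabrics accumulate holes faster); brands absent
#'   from the vector get multiplier 1.
#' @param missingness Per-round probability that a household is unvisited.
#' @param rounds Strictly increasing survey month offsets.
#' @param misreport_notfound Probability that a discard-family loss is
#'   reported NOT_FOUND (unconfirmed) at the first post-failure visit before
#'   being confirmed DISCARDED at a later visit.
#' @param present_notfound Probability that a net actually present is
#'   reported NOT_FOUND at a single visit (temporarily unlocatable).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_households = 50, seed = 42)
#' cohort <- simulate_cohort(cfg)
#' head(cohort$roster)
#' @export
cohort_config <- function(n_households = 1700,
                          nets_per_household = 1.3,
                          brand_survival = default_brand_survival(),
                          zone_mix = 0.5,
                          zone_log_odds = 0.924,
                          household_sd = 0.5,
                          cause_weights = default_cause_weights(),
                          hole_rates = c(8, 2, 0.4, 0.10),
                          hole_brand_multiplier = c("Interceptor" = 2.0,
                                                    "Olyset Net" = 1.5,
                                                    "PermaNet 2.0 C" = 0.7),
                          missingness = c(0, 0.25, 0.50, 0.95),
                          rounds = c(6, 12, 24, 36),
                          misreport_notfound = 0.15,
                          present_notfound = 0.02,
                          seed = 1L) {
  brand_survival <- as.matrix(brand_survival)
  if (is.null(rownames(brand_survival)) || nrow(brand_survival) < 1)
    stop("brand_survival must have at least one named brand row")
  if (ncol(brand_survival) != length(rounds))
    stop("brand_survival needs one column per interval (", length(rounds), ")")
  if (any(brand_survival <= 0) || any(brand_survival > 1))
    stop("brand survival probabilities must lie in (0, 1]")
  if (n_households < 1) stop("n_households must be >= 1")
  if (nets_per_household < 1) stop("nets_per_household mean must be >= 1")
  if (zone_mix < 0 || zone_mix > 1) stop("zone_mix must lie in [0, 1]")
  if (household_sd < 0) stop("household_sd must be >= 0")
  if (is.unsorted(rounds, strictly = TRUE)) stop("rounds must be strictly increasing")
  cause_weights <- as.matrix(cause_weights)
  if (nrow(cause_weights) != length(rounds))
    stop("cause_weights needs one row per round")
  if (is.null(colnames(cause_weights)) ||
      !identical(sort(colnames(cause_weights)), sort(CAUSE_LEVELS)))
    stop("cause_weights columns must be named: ", paste(CAUSE_LEVELS, collapse = ", "))
  cause_weights <- cause_weights[, CAUSE_LEVELS, drop = FALSE]
  if (any(cause_weights < 0)) stop("cause weights must be nonnegative")
  if (any(rowSums(cause_weights) <= 0)) stop("cause weights must have positive sum per round")
  if (length(missingness) != length(rounds))
    stop("missingness needs one probability per round")
  if (any(missingness < 0) || any(missingness > 1))
    stop("missingness probabilities must lie in [0, 1]")
  if (length(hole_rates) != 4 || any(hole_rates < 0))
    stop("hole_rates must be 4 nonnegative per-year rates")
  for (p in c(misreport_notfound, present_notfound))
    if (p < 0 || p > 1) stop("reporting probabilities must lie in [0, 1]")
  structure(list(n_households = as.integer(n_households),
                 nets_per_household = nets_per_household,
                 brand_survival = brand_survival,
                 zone_mix = zone_mix,
                 zone_log_odds = zone_log_odds,
                 household_sd = household_sd,
                 cause_weights = cause_weights,
                 hole_rates = hole_rates,
                 hole_brand_multiplier = hole_brand_multiplier,
                 missingness = missingness,
                 rounds = rounds,
                 misreport_notfound = misreport_notfound,
                 present_notfound = present_notfound,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Draw attrition causes
#'
#' Samples causes of net loss with probability proportional to the supplied
#' round-specific weights over the five field categories: given away, stolen,
#' exchanged, damaged and discarded, used for other purposes (repurposed).
#'
#' @param n Number of draws.
#' @param weights Nonnegative named weights over [attrition_causes()] (names
#'   optional if already in canonical order); must not be all zero.
#' @return Character vector of cause labels.
#' @examples
#' table(sample_loss_cause(1000, c(42, 8, 20, 10, 1)))
#' @export
sample_loss_cause <- function(n, weights) {
  if (length(weights) != length(CAUSE_LEVELS))
    stop("weights must have one entry per cause")
  if (!is.null(names(weights))) {
    if (!identical(sort(names(weights)), sort(CAUSE_LEVELS)))
      stop("weight names must be: ", paste(CAUSE_LEVELS, collapse = ", "))
    weights <- weights[CAUSE_LEVELS]
  }
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative with positive sum")
  if (n == 0) return(character(0))
  sample(CAUSE_LEVELS, n, replace = TRUE, prob = weights)
}

#' Simulate a longitudinal net cohort
#'
#' Generates a net roster, per-round observations and a true-parameter
#' manifest under the discrete-time survival process described in
#' [cohort_config()]. A net survives each inter-round interval with
#' probability `plogis(qlogis(s[brand, k]) + zone_log_odds * rural + u_h)`
#' where `u_h ~ N(0, household_sd^2)`. At its failure interval a cause is
#' drawn from the round's cause weights; give-away-family causes make the net
#' NOT_FOUND at later visits, discard-family causes make it DISCARDED.
#' Attrition is absorbing: a lost net never re-enters. Hole counts accumulate
#' by per-interval Poisson arrivals, so they are nondecreasing for surviving
#' nets. Observation rows exist only for rounds at which the household was
#' visited.
#'
#' @param config A [cohort_config()] object.
#' @return List of class `net_cohort` with elements
#'   \describe{
#'     \item{roster}{data frame: `net_id`, `household_id`, `brand`, `zone`,
#'       `distribution_date`.}
#'     \item{observations}{data frame: `net_id`, `round_months`, `status`
#'       (PRESENT / DISCARDED / NOT_FOUND), `reason`, `holes1`..`holes4`.}
#'     \item{true_params}{class `true_params`: the exact generative
#'       parameters (brand survival, zone log-odds, household sd, cause
#'       weights, rounds, seed).}
#'     \item{latent}{data frame of per-net ground truth: failure interval
#'       (NA if the net survived past the last round) and cause.}
#'   }
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_households = 30, seed = 7))
#' table(cohort$observations$status)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  K <- length(config$rounds)
  brands <- rownames(config$brand_survival)

  ## households: zone, random effect, brand (one product per household)
  H <- config$n_households
  hh_id <- sprintf("H%05d", seq_len(H))
  hh_zone <- ifelse(stats::runif(H) < config$zone_mix, "rural", "urban")
  hh_u <- stats::rnorm(H, 0, config$household_sd)
  hh_brand <- sample(brands, H, replace = TRUE)
  n_nets_hh <- 1L + stats::rpois(H, config$nets_per_household - 1)

  net_hh <- rep(seq_len(H), n_nets_hh)
  n <- length(net_hh)
  net_id <- sprintf("N%06d", seq_len(n))
  roster <- data.frame(net_id = net_id,
                       household_id = hh_id[net_hh],
                       brand = hh_brand[net_hh],
                       zone = hh_zone[net_hh],
                       distribution_date = "2015-01-01",
                       stringsAsFactors = FALSE)

  ## latent survival process: fail_interval = first interval not survived
  b_idx <- match(roster$brand, brands)
  rural <- as.numeric(roster$zone == "rural")
  u <- hh_u[net_hh]
  fail_interval <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  for (k in seq_len(K)) {
    eta <- stats::qlogis(config$brand_survival[cbind(b_idx, k)]) +
      config$zone_log_odds * rural + u
    survive <- stats::runif(n) < stats::plogis(eta)
    newly_dead <- alive & !survive
    fail_interval[newly_dead] <- k
    alive <- alive & survive
  }
  cause <- rep(NA_character_, n)
  for (k in seq_len(K)) {
    idx <- which(!is.na(fail_interval) & fail_interval == k)
    cause[idx] <- sample_loss_cause(length(idx), config$cause_weights[k, ])
  }

  ## hole accumulation (cumulative Poisson arrivals per interval)
  mult <- rep(1, n)
  if (length(config$hole_brand_multiplier)) {
    m <- config$hole_brand_multiplier[roster$brand]
    mult <- ifelse(is.na(m), 1, m)
  }
  interval_years <- diff(c(0, config$rounds)) / 12
  holes <- array(0L, dim = c(n, K, 4))
  for (k in seq_len(K)) {
    prev <- if (k == 1) matrix(0L, n, 4) else matrix(holes[, k - 1, ], ncol = 4)
    for (s in 1:4) {
      lam <- config$hole_rates[s] * interval_years[k] * mult
      holes[, k, s] <- prev[, s] + stats::rpois(n, lam)
    }
  }

  ## visits (household level), then observation rows
  visited <- matrix(stats::runif(H * K) >= rep(config$missingness, each = H),
                    nrow = H)
  obs <- vector("list", K)
  for (k in seq_len(K)) {
    vis <- visited[net_hh, k]
    idx <- which(vis)
    if (!length(idx)) next
    st <- character(length(idx))
    rs <- rep(NA_character_, length(idx))
    fi <- fail_interval[idx]
    present <- is.na(fi) | fi > k
    ## present nets: occasionally unlocatable at this visit
    mis_p <- present & stats::runif(length(idx)) < config$present_notfound
    st[present] <- "PRESENT"
    st[mis_p] <- "NOT_FOUND"
    ## lost nets
    lost <- which(!present)
    if (length(lost)) {
      cz <- cause[idx[lost]]
      give_family <- cz %in% NOTFOUND_CAUSES
      st[lost[give_family]] <- "NOT_FOUND"
      rs[lost[give_family]] <- cz[give_family]
      disc <- lost[!give_family]
      if (length(disc)) {
        ## first visited round since failure may yield an unconfirmed report
        prev_vis <- rep(FALSE, length(disc))
        for (j in seq_along(disc)) {
          kk <- fail_interval[idx[disc[j]]]
          if (kk < k) prev_vis[j] <- any(visited[net_hh[idx[disc[j]]], kk:(k - 1)])
        }
        unconfirmed <- !prev_vis &
          stats::runif(length(disc)) < config$misreport_notfound
        st[disc[unconfirmed]] <- "NOT_FOUND"
        st[disc[!unconfirmed]] <- "DISCARDED"
        rs[disc[!unconfirmed]] <- cause[idx[disc[!unconfirmed]]]
      }
    }
    hv <- holes[idx, k, , drop = FALSE]
    keep_holes <- st == "PRESENT"
    ob <- data.frame(net_id = net_id[idx],
                     round_months = config$rounds[k],
                     status = st,
                     reason = rs,
                     holes1 = ifelse(keep_holes, hv[, 1, 1], NA_integer_),
                     holes2 = ifelse(keep_holes, hv[, 1, 2], NA_integer_),
                     holes3 = ifelse(keep_holes, hv[, 1, 3], NA_integer_),
                     holes4 = ifelse(keep_holes, hv[, 1, 4], NA_integer_),
                     stringsAsFactors = FALSE)
    obs[[k]] <- ob
  }
  observations <- do.call(rbind, obs)
  rownames(observations) <- NULL

  true_params <- structure(list(brand_survival = config$brand_survival,
                                zone_log_odds = config$zone_log_odds,
                                household_sd = config$household_sd,
                                cause_weights = config$cause_weights,
                                rounds = config$rounds,
                                seed = config$seed),
                           class = "true_params")
  latent <- data.frame(net_id = net_id,
                       fail_interval = fail_interval,
                       cause = cause,
                       stringsAsFactors = FALSE)
  structure(list(roster = roster, observations = observations,
                 true_params = true_params, latent = latent),
            class = "net_cohort")
}

#' @export
print.net_cohort <- function(x, ...) {
  cat("Synthetic net cohort:", nrow(x$roster), "nets in",
      length(unique(x$roster$household_id)), "households,",
      length(unique(x$roster$brand)), "brands\n")
  cat("Rounds (months):", paste(x$true_params$rounds, collapse = ", "), "\n")
  cat("Observation rows:", nrow(x$observations), "\n")
  invisible(x)
}

#' Write / read a cohort as delimited text plus a manifest
#'
#' `write_cohort()` writes `roster.csv`, `observations.csv` and a
#' `true_params.yaml` manifest into a directory; `read_cohort()` reads them
#' back. The manifest round-trips losslessly, enabling parameter-recovery
#' tests against the exact generative values.
#'
#' @param cohort A `net_cohort` object.
#' @param dir Directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a `net_cohort` (without the latent truth table, which is not persisted).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "net_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$roster, file.path(dir, "roster.csv"), row.names = FALSE)
  utils::write.csv(cohort$observations, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  write_true_params(cohort$true_params, file.path(dir, "true_params.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  roster <- utils::read.csv(file.path(dir, "roster.csv"),
                            colClasses = "character")
  observations <- utils::read.csv(file.path(dir, "observations.csv"),
                                  stringsAsFactors = FALSE)
  observations$net_id <- as.character(observations$net_id)
  tp <- read_true_params(file.path(dir, "true_params.yaml"))
  structure(list(roster = roster, observations = observations,
                 true_params = tp, latent = NULL), class = "net_cohort")
}

#' @rdname write_cohort
#' @param params A `true_params` object.
#' @param path File path for the YAML manifest.
#' @export
write_true_params <- function(params, path) {
  stopifnot(inherits(params, "true_params"))
  x <- list(brands = rownames(params$brand_survival),
            brand_survival = apply(params$brand_survival, 1, as.numeric,
                                   simplify = FALSE),
            zone_log_odds = params$zone_log_odds,
            household_sd = params$household_sd,
            cause_weights = apply(params$cause_weights, 1, function(r)
              as.list(stats::setNames(as.numeric(r), colnames(params$cause_weights))),
              simplify = FALSE),
            rounds = params$rounds,
            seed = params$seed)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_true_params <- function(path) {
  x <- yaml::read_yaml(path)
  bs <- do.call(rbind, x$brand_survival)
  rownames(bs) <- x$brands
  colnames(bs) <- paste0("i", seq_len(ncol(bs)))
  cw <- do.call(rbind, lapply(x$cause_weights, function(r) unlist(r[CAUSE_LEVELS])))
  rownames(cw) <- paste0("round", seq_len(nrow(cw)))
  structure(list(brand_survival = bs,
                 zone_log_odds = x$zone_log_odds,
                 household_sd = x$household_sd,
                 cause_weights = cw,
                 rounds = as.numeric(x$rounds),
                 seed = as.integer(x$seed)),
            class = "true_params")
}
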