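## Bayesian discrete-time survival model with household random effects and
## Gibbs-sampled data augmentation of ambiguous net statuses.
##
## Each net contributes one Bernoulli trial per inter-round interval it is at
## risk in: "survive" means still present in the household at the end of the
## interval. Failure is absence for any reason (given away, stolen,
## exchanged, destroyed, repurposed); UNSURVEYED tails are right-censored;
## optionally the give-away family can be censored instead of counted as
## failure. Conditional interval survival is modelled on the log-odds scale,
##   logit Pr(present at k | present at k-1) = alpha[b,k] (+ beta * rural)
##                                             + u_household,
##   u_h ~ Normal(0, sigma^2),
## with weakly informative priors Normal(0, 2.5^2) on alpha and beta and
## half-Normal(1) on sigma. Unequal interval lengths are handled by giving
## each interval its own parameter, never by rescaling hazards.
##
## A net last seen present at round a and first known absent at round d > a+1
## has a latent failure interval f in {a+1, ..., d}; the cleaned matrix's
## UNKNOWN (and interleaved UNSURVEYED) cells inside that window are what f
## resolves. The Gibbs sampler alternates (i) drawing each f from its full
## conditional -- proportional to survival through f-1 times failure at f,
## zero mass after a known DISCARDED -- and (ii) updating parameters given
## the completed data: conjugate Beta draws when interval survivals are
## modelled directly on the probability scale (per-brand variant without
## random effects), Metropolis-within-Gibbs on the logit-scale parameters
## otherwise. Imputed trajectories are monotone by construction: presence at
## rounds before f, absence from f on.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

bern_ll <- function(eta, y) y * eta - softplus(eta)

## sum v by integer group id into G bins
group_sum <- function(v, g, G) {
  out <- numeric(G)
  if (length(v)) {
    s <- rowsum(v, g)
    out[as.integer(rownames(s))] <- s
  }
  out
}

#' Full conditional of a latent failure interval
#'
#' For a net present at round `a` and first known absent at round `d`, the
#' latent failure interval lies in `a+1, ..., d`. Given the conditional
#' survival probabilities `p` of those intervals (length `d - a`), the
#' probability that failure occurred at the j-th interval of the window is
#' proportional to `prod(p[1:(j-1)]) * (1 - p[j])`. The vector is normalised
#' to sum to one; a degenerate all-zero conditional (every `p` equal to 1)
#' resolves to failure at the earliest interval, the convention the sampler
#' also uses (with a logged count).
#'
#' @param p Numeric vector of conditional interval survival probabilities in
#'   [0, 1] for the window.
#' @return Numeric probability vector of the same length.
#' @examples
#' failure_interval_probs(c(0.5, 0.5))  # 2/3 early, 1/3 late
#' failure_interval_probs(c(0.5, 0))    # even split
#' @export
failure_interval_probs <- function(p) {
  stopifnot(length(p) >= 1, all(p >= 0), all(p <= 1))
  w <- cumprod(c(1, p[-length(p)])) * (1 - p)
  s <- sum(w)
  if (s <= 0) return(c(1, rep(0, length(p) - 1)))
  w / s
}

## --- data preparation -------------------------------------------------

prepare_model_data <- function(m, roster = NULL, variant, censor_not_found) {
  stopifnot(inherits(m, "cohort_matrix"))
  if (is.null(roster)) roster <- m$roster
  idx <- match(rownames(m$status), roster$net_id)
  if (anyNA(idx)) stop("roster is missing nets present in the matrix")
  roster <- roster[idx, , drop = FALSE]
  st <- m$status
  K <- ncol(st)
  n <- nrow(st)
  absent_codes <- if (censor_not_found) "DISCARDED" else c("DISCARDED", "NOT_FOUND")

  a <- integer(n); d <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    w <- which(st[i, ] == "PRESENT")
    a[i] <- if (length(w)) w[length(w)] else 0L
    wd <- which(st[i, ] %in% absent_codes)
    wd <- wd[wd > a[i]]
    if (length(wd)) d[i] <- wd[1]
  }

  brands <- sort(unique(roster$brand))
  b_idx <- match(roster$brand, brands)
  hh <- match(roster$household_id, unique(roster$household_id))
  H <- max(hh)
  rural <- as.numeric(roster$zone == "rural")
  G <- if (variant == "brand") length(brands) * K else K
  gid_of <- function(b, k) if (variant == "brand") (b - 1L) * K + k else k

  ## fixed Bernoulli rows: survived intervals 1..a; failure at d when d==a+1
  f1_net <- rep(seq_len(n), a)
  f1_k <- sequence(a)
  known_fail <- which(!is.na(d) & d == a + 1L)
  fx_net <- c(f1_net, known_fail)
  fx_k <- c(f1_k, d[known_fail])
  fixed <- list(gid = gid_of(b_idx[fx_net], fx_k),
                hh = hh[fx_net], rural = rural[fx_net],
                y = c(rep(1, length(f1_net)), rep(0, length(known_fail))))

  ## latent windows: d finite and d > a + 1
  lat <- which(!is.na(d) & d > a + 1L)
  win <- NULL
  if (length(lat)) {
    len <- d[lat] - a[lat]
    wnet <- rep(lat, len)
    wk <- sequence(len, from = a[lat] + 1L)
    wg <- rep(seq_along(lat), len)
    win <- list(net = wnet, k = wk, group = wg,
                gid = gid_of(b_idx[wnet], wk),
                hh = hh[wnet], rural = rural[wnet],
                len = len, first = cumsum(c(1L, len[-length(len)])),
                a = a[lat], d = d[lat], net_id = rownames(st)[lat])
  }
  list(n = n, K = K, H = H, G = G, brands = brands, b_idx = b_idx, hh = hh,
       rural = rural, a = a, d = d, fixed = fixed, win = win,
       n_latent = length(lat), variant = variant, rounds = m$rounds,
       net_id = rownames(st), roster = roster)
}

## sample latent failure intervals given window survival probabilities p_win
## (aligned with win rows); returns list(f, n_degenerate)
sample_failure <- function(win, p_win, u) {
  w <- cumprod_window(log(pmax(p_win, 1e-300)), win) # log survival before row
  wgt <- exp(w) * (1 - p_win)
  tot <- group_sum(wgt, win$group, length(win$len))
  degen <- tot <= 0
  tot[degen] <- 1
  target <- u * tot
  cw0 <- c(0, cumsum(wgt))
  within <- cw0[seq_along(wgt) + 1L] - rep(cw0[win$first], win$len)
  hit <- within >= target[win$group] - 1e-12
  sel <- which(hit)
  first_sel <- sel[!duplicated(win$group[sel])]
  f <- integer(length(win$len))
  f[win$group[first_sel]] <- win$k[first_sel]
  ## degenerate groups (all survival 1): fail at earliest interval
  if (any(degen)) f[degen] <- win$a[degen] + 1L
  ## safety: any group not hit (numerical) -> latest interval
  miss <- f == 0L
  if (any(miss)) f[miss] <- win$d[miss]
  list(f = f, n_degenerate = sum(degen))
}

## cumulative sum of lp within window groups, exclusive of the current row
cumprod_window <- function(lp, win) {
  cs0 <- c(0, cumsum(lp))
  cs0[seq_along(lp)] - rep(cs0[win$first], win$len)
}

## Bernoulli rows contributed by the current latent failure draws
latent_obs <- function(win, f) {
  len <- f - win$a
  idx <- sequence(len, from = win$first)
  y <- as.numeric(win$k[idx] < rep(f, len))
  list(gid = win$gid[idx], hh = win$hh[idx], rural = win$rural[idx], y = y,
       idx = idx)
}

## --- the fitting function ---------------------------------------------

#' Fit the Bayesian discrete-time net survival model
#'
#' Fits, by Gibbs sampling with data augmentation, a discrete-time survival
#' model to a cleaned cohort matrix. The event is absence of the net from
#' the household for any reason; UNSURVEYED tails are right-censored. Two
#' variants are available: `"brand"` estimates independent interval survival
#' probabilities per product type; `"zone"` pools products and adds a rural
#' log-odds term whose exponential is the rural-vs-urban odds ratio of
#' interval survival. Household random effects on the logit scale capture
#' within-household clustering. Latent failure intervals of nets with
#' ambiguous (UNKNOWN) or unobserved cells between their last confirmed
#' presence and first confirmed absence are imputed within each iteration
#' from their full conditionals, with zero probability of presence after a
#' DISCARDED assignment.
#'
#' With `household_re = FALSE` and `variant = "brand"`, interval survivals
#' are modelled directly on the probability scale with Beta(1, 1) priors and
#' updated by conjugate Beta draws, so that in the absence of missing data
#' the posterior is the closed-form Beta posterior. Otherwise parameters are
#' updated by adaptive random-walk Metropolis within Gibbs on the logit
#' scale.
#'
#' @param m A cleaned `cohort_matrix` (see [clean_status_matrix()]).
#' @param roster Roster data frame; defaults to the one carried by `m`.
#' @param variant `"brand"` or `"zone"`.
#' @param household_re Include household random effects (default TRUE).
#' @param chains,iter,burnin,thin MCMC settings; `iter` is per chain and
#'   includes `burnin`. At least 2 chains are required for split-Rhat.
#' @param prior_sd_alpha,prior_sd_beta Normal prior SDs of the logit-scale
#'   intercepts and of the rural coefficient.
#' @param prior_scale_sigma Scale of the half-Normal prior on the household
#'   effect SD.
#' @param censor_not_found Treat give-away-family absences (NOT_FOUND) as
#'   censoring instead of failure (default FALSE: absence for any reason is
#'   the event).
#' @param keep_latent Store the per-iteration latent failure draws (needed
#'   to inspect imputed trajectories).
#' @param rhat_threshold Convergence flag threshold on split-Rhat.
#' @param seed Integer seed; each chain uses a deterministic sub-seed.
#' @return Object of class `net_survival_fit` with posterior draws, data
#'   summaries and diagnostics. Use [summary.net_survival_fit()],
#'   [posterior_survival()], [zone_effect()], `coef()`, `plot()`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_households = 60, seed = 3))
#' m <- clean_status_matrix(
#'   build_status_matrix(cohort$roster, cohort$observations, c(6, 12, 24, 36)))
#' fit <- fit_net_survival(m, variant = "zone", chains = 2, iter = 400,
#'                         burnin = 200, seed = 1)
#' zone_effect(fit)
#' @export
fit_net_survival <- function(m, roster = NULL,
                             variant = c("brand", "zone"),
                             household_re = TRUE,
                             chains = 4, iter = 5000, burnin = 2500, thin = 1,
                             prior_sd_alpha = 2.5, prior_sd_beta = 2.5,
                             prior_scale_sigma = 1,
                             censor_not_found = FALSE,
                             keep_latent = FALSE,
                             rhat_threshold = 1.01,
                             seed = 1L) {
  variant <- match.arg(variant)
  if (iter <= burnin) stop("iter must exceed burnin")
  if (chains < 2) warning("fewer than 2 chains: split-Rhat is unreliable")
  dat <- prepare_model_data(m, roster, variant, censor_not_found)
  conjugate <- (variant == "brand") && !household_re

  ## groups that can never receive data: sampled from the prior
  max_gid <- c(dat$fixed$gid, if (!is.null(dat$win)) dat$win$gid)
  empty <- setdiff(seq_len(dat$G), unique(max_gid))
  if (length(empty))
    warning(length(empty), " brand-interval cell(s) have no data; ",
            "their survival is sampled from the prior")

  keep_iters <- seq.int(burnin + 1L, iter, by = thin)
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    chain_seed <- (seed + 104729 * (ch - 1L)) %% .Machine$integer.max
    set.seed(chain_seed)
    res[[ch]] <- run_chain(dat, conjugate, household_re, iter, keep_iters,
                           burnin, prior_sd_alpha, prior_sd_beta,
                           prior_scale_sigma, keep_latent)
  }
  combine_chains(res, dat, conjugate, household_re, variant, chains,
                 iter, burnin, thin, rhat_threshold, keep_latent,
                 list(prior_sd_alpha = prior_sd_alpha,
                      prior_sd_beta = prior_sd_beta,
                      prior_scale_sigma = prior_scale_sigma,
                      censor_not_found = censor_not_found, seed = seed),
                 match.call())
}

run_chain <- function(dat, conjugate, household_re, iter, keep_iters, burnin,
                      psd_a, psd_b, psc_s, keep_latent) {
  G <- dat$G; H <- dat$H; K <- dat$K
  zone <- dat$variant == "zone"
  win <- dat$win
  n_lat <- dat$n_latent
  fixed <- dat$fixed

  ## initial values
  f <- if (n_lat) win$d else integer(0)   # fail at detection round
  alpha <- rep(0, G)                      # logit scale (ignored if conjugate)
  s <- rep(0.5, G)                        # probability scale
  beta <- 0
  u <- rep(0, H)
  sigma <- if (household_re) psc_s / 2 else 0

  ## crude empirical initialisation for alpha
  obs0 <- if (n_lat) {
    lo <- latent_obs(win, f)
    list(gid = c(fixed$gid, lo$gid), y = c(fixed$y, lo$y))
  } else fixed
  n0 <- group_sum(rep(1, length(obs0$gid)), obs0$gid, G)
  s0 <- (group_sum(obs0$y, obs0$gid, G) + 1) / (n0 + 2)
  alpha <- stats::qlogis(pmin(pmax(s0, 0.05), 0.95))
  s <- s0

  scale_a <- rep(0.4, G); scale_u <- rep(0.8, H); scale_b <- 0.2; scale_s <- 0.4
  acc_a <- num_a <- rep(0, G); acc_u <- num_u <- rep(0, H)
  acc_b <- num_b <- 0; acc_s <- num_s <- 0

  n_keep <- length(keep_iters)
  S_draw <- matrix(NA_real_, n_keep, G)    # survival probability scale
  beta_draw <- numeric(n_keep)
  sigma_draw <- numeric(n_keep)
  f_draw <- if (keep_latent && n_lat) matrix(NA_integer_, n_keep, n_lat) else NULL
  n_degenerate <- 0L
  store <- 0L
  keep_flag <- logical(iter)
  keep_flag[keep_iters] <- TRUE

  hh_has_obs <- rep(FALSE, H)
  hh_all <- c(fixed$hh, if (n_lat) win$hh)
  hh_has_obs[unique(hh_all)] <- TRUE

  for (it in seq_len(iter)) {
    ## 1. latent failure intervals
    if (n_lat) {
      p_win <- if (conjugate) s[win$gid]
      else stats::plogis(alpha[win$gid] + beta * win$rural + u[win$hh])
      sf <- sample_failure(win, p_win, stats::runif(n_lat))
      f <- sf$f
      n_degenerate <- n_degenerate + sf$n_degenerate
      lo <- latent_obs(win, f)
      gid <- c(fixed$gid, lo$gid); hh <- c(fixed$hh, lo$hh)
      rural <- c(fixed$rural, lo$rural); y <- c(fixed$y, lo$y)
    } else {
      gid <- fixed$gid; hh <- fixed$hh; rural <- fixed$rural; y <- fixed$y
    }

    ## 2. parameters
    if (conjugate) {
      nn <- group_sum(rep(1, length(gid)), gid, G)
      sv <- group_sum(y, gid, G)
      s <- stats::rbeta(G, 1 + sv, 1 + nn - sv)
    } else {
      eta <- alpha[gid] + beta * rural + u[hh]
      ll <- bern_ll(eta, y)
      ## alpha: independent random-walk MH per group
      da <- stats::rnorm(G, 0, scale_a)
      ll_new <- bern_ll(eta + da[gid], y)
      delta <- group_sum(ll_new - ll, gid, G) +
        stats::dnorm(alpha + da, 0, psd_a, log = TRUE) -
        stats::dnorm(alpha, 0, psd_a, log = TRUE)
      acc <- log(stats::runif(G)) < delta
      alpha[acc] <- alpha[acc] + da[acc]
      num_a <- num_a + 1; acc_a <- acc_a + acc
      eta <- alpha[gid] + beta * rural + u[hh]
      ll <- bern_ll(eta, y)
      ## beta (zone variant)
      if (zone) {
        db <- stats::rnorm(1, 0, scale_b)
        delta <- sum(bern_ll(eta + db * rural, y) - ll) +
          stats::dnorm(beta + db, 0, psd_b, log = TRUE) -
          stats::dnorm(beta, 0, psd_b, log = TRUE)
        if (log(stats::runif(1)) < delta) {
          beta <- beta + db
          eta <- eta + db * rural
          ll <- bern_ll(eta, y)
          acc_b <- acc_b + 1
        }
        num_b <- num_b + 1
      }
      ## household effects
      if (household_re) {
        du <- stats::rnorm(H, 0, scale_u)
        ll_new <- bern_ll(eta + du[hh], y)
        delta <- group_sum(ll_new - ll, hh, H) +
          stats::dnorm(u + du, 0, sigma, log = TRUE) -
          stats::dnorm(u, 0, sigma, log = TRUE)
        acc <- log(stats::runif(H)) < delta
        u[acc] <- u[acc] + du[acc]
        ## households without any observation: exact draw from the prior
        no_obs <- !hh_has_obs
        if (any(no_obs)) u[no_obs] <- stats::rnorm(sum(no_obs), 0, sigma)
        num_u <- num_u + 1; acc_u <- acc_u + acc
        ## sigma: MH on log scale, half-Normal(psc_s) prior
        ls <- log(sigma)
        ls_new <- ls + stats::rnorm(1, 0, scale_s)
        s_new <- exp(ls_new)
        delta <- sum(stats::dnorm(u, 0, s_new, log = TRUE)) -
          sum(stats::dnorm(u, 0, sigma, log = TRUE)) +
          (-s_new^2 / (2 * psc_s^2)) - (-sigma^2 / (2 * psc_s^2)) +
          ls_new - ls
        if (log(stats::runif(1)) < delta) { sigma <- s_new; acc_s <- acc_s + 1 }
        num_s <- num_s + 1
      }
      ## adapt proposal scales during burn-in
      if (it <= burnin && it %% 50 == 0) {
        scale_a <- pmin(pmax(scale_a * exp(acc_a / num_a - 0.4), 0.02), 5)
        acc_a <- num_a <- rep(0, G)
        if (household_re) {
          scale_u <- pmin(pmax(scale_u * exp(acc_u / num_u - 0.4), 0.05), 5)
          acc_u <- num_u <- rep(0, H)
          if (num_s > 0) {
            scale_s <- min(max(scale_s * exp(acc_s / num_s - 0.4), 0.02), 3)
            acc_s <- num_s <- 0
          }
        }
        if (zone && num_b > 0) {
          scale_b <- min(max(scale_b * exp(acc_b / num_b - 0.4), 0.01), 3)
          acc_b <- num_b <- 0
        }
      }
      s <- stats::plogis(alpha)
    }

    ## 3. store
    if (keep_flag[it]) {
      store <- store + 1L
      S_draw[store, ] <- s
      beta_draw[store] <- beta
      sigma_draw[store] <- sigma
      if (!is.null(f_draw)) f_draw[store, ] <- f
    }
  }
  list(s = S_draw, beta = beta_draw, sigma = sigma_draw, f = f_draw,
       n_degenerate = n_degenerate,
       accept = list(alpha = if (!conjugate) mean(acc_a / pmax(num_a, 1)) else NA))
}

combine_chains <- function(res, dat, conjugate, household_re, variant, chains,
                           iter, burnin, thin, rhat_threshold, keep_latent,
                           priors, call) {
  s <- do.call(rbind, lapply(res, `[[`, "s"))
  beta <- unlist(lapply(res, `[[`, "beta"))
  sigma <- unlist(lapply(res, `[[`, "sigma"))
  n_keep <- nrow(res[[1]]$s)
  chain_id <- rep(seq_len(chains), each = n_keep)
  f <- if (keep_latent && dat$n_latent)
    do.call(rbind, lapply(res, `[[`, "f")) else NULL

  ## parameter names
  K <- dat$K
  if (variant == "brand") {
    pn <- as.vector(t(outer(dat$brands, seq_len(K),
                            function(b, k) sprintf("s[%s,%d]", b, k))))
    ## columns of s are ordered gid = (b-1)*K + k
    colnames(s) <- pn
  } else {
    colnames(s) <- sprintf("s[%d]", seq_len(K))
  }

  rhats <- c(apply(s, 2, split_rhat, chain_id = chain_id),
             if (variant == "zone") c(beta = split_rhat(beta, chain_id)),
             if (household_re) c(sigma = split_rhat(sigma, chain_id)))
  structure(list(variant = variant, conjugate = conjugate,
                 household_re = household_re,
                 brands = dat$brands, K = K, rounds = dat$rounds,
                 draws = list(s = s, beta = beta, sigma = sigma, f = f),
                 chain_id = chain_id,
                 data = list(n_nets = dat$n, n_households = dat$H,
                             n_latent = dat$n_latent,
                             latent_net_id = if (!is.null(dat$win)) dat$win$net_id,
                             win = dat$win),
                 n_degenerate = sum(vapply(res, `[[`, integer(1), "n_degenerate")),
                 mcmc = list(chains = chains, iter = iter, burnin = burnin,
                             thin = thin),
                 priors = priors,
                 rhat = rhats,
                 converged = all(rhats < rhat_threshold, na.rm = TRUE),
                 rhat_threshold = rhat_threshold,
                 call = call),
            class = "net_survival_fit")
}

#' Split-half Rhat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (so within-chain trends inflate the diagnostic).
#'
#' @param x Numeric vector of draws, chains stacked.
#' @param chain_id Integer chain index per draw.
#' @return Rhat (>= 1; NA for constant draws).
#' @export
split_rhat <- function(x, chain_id) {
  halves <- split(x, chain_id)
  sub <- unlist(lapply(halves, function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[seq.int(h + 1, 2 * h)])
  }), recursive = FALSE)
  mns <- vapply(sub, mean, numeric(1))
  vrs <- vapply(sub, stats::var, numeric(1))
  m <- length(sub); n <- length(sub[[1]])
  W <- mean(vrs); B <- n * stats::var(mns)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}
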