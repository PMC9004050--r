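## Methods for net_survival_fit objects.

#' @export
print.net_survival_fit <- function(x, ...) {
  cat("Bayesian discrete-time net survival model (",
      if (x$variant == "brand") "per-brand" else "zone-covariate",
      " variant", if (x$conjugate) ", conjugate" else "", ")\n", sep = "")
  cat("  nets:", x$data$n_nets, " households:", x$data$n_households,
      " latent failure windows:", x$data$n_latent, "\n")
  cat("  MCMC:", x$mcmc$chains, "chains x", x$mcmc$iter, "iterations (",
      x$mcmc$burnin, "burn-in, thin", x$mcmc$thin, ")\n")
  cat("  max split-Rhat:", round(max(x$rhat, na.rm = TRUE), 4),
      if (x$converged) "(converged)" else
        paste0("(above threshold ", x$rhat_threshold, " for some parameters)"),
      "\n")
  if (x$variant == "zone") {
    b <- x$draws$beta
    cat(sprintf("  rural coefficient: %.3f (OR %.2f)\n", mean(b), mean(exp(b))))
  }
  invisible(x)
}

ci_quantiles <- function(level) c((1 - level) / 2, 1 - (1 - level) / 2)

#' Summarise a fitted net survival model
#'
#' Posterior means, standard deviations, equal-tailed credible intervals and
#' split-Rhat for the interval survival probabilities, the cumulative
#' survival per round (per brand, or per zone for the zone variant), the
#' household effect scale and — for the zone variant — the rural coefficient
#' and its odds ratio.
#'
#' @param object A `net_survival_fit`.
#' @param level Credible level in (0, 1); default 0.95.
#' @param ... Unused.
#' @return Data frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`, `rhat`.
#' @export
summary.net_survival_fit <- function(object, level = 0.95, ...) {
  if (level <= 0 || level >= 1) stop("level must lie strictly between 0 and 1")
  q <- ci_quantiles(level)
  rows <- list()
  add <- function(name, draws, rhat = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = name, mean = mean(draws), sd = stats::sd(draws),
      lower = as.numeric(stats::quantile(draws, q[1])),
      upper = as.numeric(stats::quantile(draws, q[2])), rhat = rhat)
  }
  s <- object$draws$s
  for (j in seq_len(ncol(s))) add(colnames(s)[j], s[, j], object$rhat[j])
  ## cumulative survival within each draw
  S <- cumulative_survival_draws(object)
  for (nm in colnames(S$ref)) add(nm, S$ref[, nm])
  if (!is.null(S$rural)) for (nm in colnames(S$rural)) add(nm, S$rural[, nm])
  if (object$variant == "zone") {
    add("beta", object$draws$beta, object$rhat[["beta"]])
    add("OR", exp(object$draws$beta))
  }
  if (object$household_re)
    add("sigma", object$draws$sigma, object$rhat[["sigma"]])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## per-draw cumulative survival; "ref" is per brand (brand variant) or the
## urban stratum (zone variant); "rural" only for the zone variant
cumulative_survival_draws <- function(fit) {
  K <- fit$K
  rounds <- if (!is.null(fit$rounds)) fit$rounds else seq_len(K)
  s <- fit$draws$s
  if (fit$variant == "brand") {
    B <- length(fit$brands)
    ref <- matrix(NA_real_, nrow(s), B * K)
    nms <- character(B * K)
    for (b in seq_len(B)) {
      cols <- (b - 1) * K + seq_len(K)
      ref[, cols] <- t(apply(s[, cols, drop = FALSE], 1, cumprod))
      nms[cols] <- sprintf("S[%s,m%g]", fit$brands[b], rounds)
    }
    colnames(ref) <- nms
    list(ref = ref, rural = NULL)
  } else {
    ref <- t(apply(s, 1, cumprod))
    colnames(ref) <- sprintf("S[urban,m%g]", rounds)
    sr <- stats::plogis(stats::qlogis(s) + fit$draws$beta)
    rural <- t(apply(sr, 1, cumprod))
    colnames(rural) <- sprintf("S[rural,m%g]", rounds)
    list(ref = ref, rural = rural)
  }
}

#' Posterior cumulative survival table
#'
#' Posterior mean and equal-tailed credible interval of the cumulative
#' probability that a net is still present at each round, per brand (brand
#' variant) or per zone (zone variant).
#'
#' @param fit A `net_survival_fit`.
#' @param level Credible level; default 0.95.
#' @return Data frame: `group`, `round_months`, `mean`, `lower`, `upper`
#'   (probability scale).
#' @export
posterior_survival <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "net_survival_fit"))
  q <- ci_quantiles(level)
  S <- cumulative_survival_draws(fit)
  mats <- c(list(S$ref), if (!is.null(S$rural)) list(S$rural))
  out <- list()
  rounds <- if (!is.null(fit$rounds)) fit$rounds else seq_len(fit$K)
  for (M in mats) {
    info <- do.call(rbind, regmatches(colnames(M),
                                      regexec("^S\\[(.+),m([0-9.]+)\\]$", colnames(M))))
    out[[length(out) + 1L]] <- data.frame(
      group = info[, 2], round_months = as.numeric(info[, 3]),
      mean = colMeans(M),
      lower = apply(M, 2, stats::quantile, q[1]),
      upper = apply(M, 2, stats::quantile, q[2]),
      row.names = NULL)
  }
  do.call(rbind, out)
}

#' @export
coef.net_survival_fit <- function(object, ...) {
  out <- colMeans(object$draws$s)
  if (object$variant == "zone")
    out <- c(out, beta = mean(object$draws$beta))
  if (object$household_re)
    out <- c(out, sigma = mean(object$draws$sigma))
  out
}

#' Rural-versus-urban effect on net survival
#'
#' Summarises the rural coefficient of a zone-variant fit and the implied
#' odds ratio. The OR summary is computed by exponentiating the coefficient
#' draws and then summarising (the point relation `exp(mean coefficient)` is
#' also reported for comparison).
#'
#' @param fit A `net_survival_fit` with `variant = "zone"`.
#' @param level Credible level; default 0.95.
#' @return Object of class `zone_effect`: list with `coefficient` and `or`
#'   (each mean/lower/upper) and `or_of_mean`.
#' @export
zone_effect <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "net_survival_fit"))
  if (fit$variant != "zone")
    stop("zone_effect requires a fit with variant = \"zone\"")
  out <- odds_ratio_summary(fit$draws$beta, level)
  out
}

#' Odds-ratio summary of log-odds draws
#'
#' Given posterior draws of a log-odds coefficient, returns the mean and
#' equal-tailed interval of the coefficient and of its exponential (the odds
#' ratio), summarising the exponentiated draws rather than exponentiating
#' the summaries; `exp(mean coefficient)` is reported alongside.
#'
#' @param beta_draws Numeric vector of coefficient draws.
#' @param level Credible level; default 0.95.
#' @return Object of class `zone_effect`.
#' @examples
#' odds_ratio_summary(rep(0.924, 10))$or_of_mean  # exp(0.924) = 2.5 (1 d.p.)
#' @export
odds_ratio_summary <- function(beta_draws, level = 0.95) {
  q <- ci_quantiles(level)
  or <- exp(beta_draws)
  structure(list(
    coefficient = c(mean = mean(beta_draws),
                    lower = as.numeric(stats::quantile(beta_draws, q[1])),
                    upper = as.numeric(stats::quantile(beta_draws, q[2]))),
    or = c(mean = mean(or),
           lower = as.numeric(stats::quantile(or, q[1])),
           upper = as.numeric(stats::quantile(or, q[2]))),
    or_of_mean = exp(mean(beta_draws)),
    level = level), class = "zone_effect")
}

#' @export
print.zone_effect <- function(x, ...) {
  lv <- round(100 * x$level)
  cat(sprintf("Rural coefficient: %.3f (%d%% CI %.3f-%.3f)\n",
              x$coefficient["mean"], lv, x$coefficient["lower"],
              x$coefficient["upper"]))
  cat(sprintf("Odds ratio:        %.2f (%d%% CI %.2f-%.2f)  [exp(mean) = %.2f]\n",
              x$or["mean"], lv, x$or["lower"], x$or["upper"], x$or_of_mean))
  invisible(x)
}

#' Predicted cumulative survival
#'
#' Posterior mean cumulative survival at each round for a given brand (brand
#' variant) or zone (zone variant).
#'
#' @param object A `net_survival_fit`.
#' @param group Brand label or `"rural"`/`"urban"`; default all groups.
#' @param ... Unused.
#' @return Data frame as [posterior_survival()], filtered to `group`.
#' @export
predict.net_survival_fit <- function(object, group = NULL, ...) {
  ps <- posterior_survival(object)
  if (!is.null(group)) {
    if (!all(group %in% ps$group))
      stop("unknown group(s): ", paste(setdiff(group, ps$group), collapse = ", "))
    ps <- ps[ps$group %in% group, , drop = FALSE]
  }
  ps
}

#' Plot posterior survival curves
#'
#' Posterior mean cumulative survival by round with credible bands, one
#' curve per brand (or zone).
#'
#' @param x A `net_survival_fit`.
#' @param level Credible level for the bands.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.net_survival_fit <- function(x, level = 0.95, ...) {
  ps <- posterior_survival(x, level)
  groups <- unique(ps$group)
  rounds <- sort(unique(ps$round_months))
  M <- sapply(groups, function(g)
    ps$mean[ps$group == g][order(ps$round_months[ps$group == g])])
  graphics::matplot(rounds, M, type = "b", pch = 16, lty = 1,
                    xlab = "months since distribution",
                    ylab = "cumulative probability of presence",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomleft", legend = groups, col = seq_along(groups),
                   lty = 1, pch = 16, cex = 0.8, bty = "n")
  invisible(ps)
}

#' Imputed latent trajectories
#'
#' Reconstructs, for every retained MCMC iteration, the imputed
#' presence/absence of each net with a latent failure window (requires the
#' fit to have been run with `keep_latent = TRUE`). Round `r` of a window is
#' imputed PRESENT exactly when the drawn failure interval exceeds `r`, so
#' trajectories are monotone by construction; this accessor exposes them for
#' inspection.
#'
#' @param fit A `net_survival_fit` fitted with `keep_latent = TRUE`.
#' @return List with `net_id`, `windows` (per-net first/last latent round
#'   indices) and `present`, a draws x windows-cells logical matrix; plus
#'   `f`, the raw failure-interval draws.
#' @export
imputed_trajectories <- function(fit) {
  stopifnot(inherits(fit, "net_survival_fit"))
  f <- fit$draws$f
  if (is.null(f))
    stop("fit was not run with keep_latent = TRUE (or has no latent windows)")
  win <- fit$data$win
  present <- matrix(NA, nrow(f), length(win$k))
  for (it in seq_len(nrow(f)))
    present[it, ] <- win$k < f[it, win$group]
  list(net_id = win$net_id, window_net = win$group, window_round = win$k,
       present = present, f = f,
       a = win$a, d = win$d)
}
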