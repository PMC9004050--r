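## Nets-by-rounds status matrix and the monotone cleaning rules.
##
## The cleaning encodes three facts about a net's trajectory:
##   1. presence propagates backwards (a net present at 24 months was present
##      at 6 and 12 months, observed or not);
##   2. discard is absorbing and propagates forwards (a net reported
##      destroyed or repurposed stays destroyed at later rounds);
##   3. a NOT_FOUND report that precedes a later DISCARDED report is
##      genuinely ambiguous — the net may already have been destroyed or may
##      still have been present — and is marked UNKNOWN for the Bayesian
##      sampler to resolve.
## The rules are applied in the order backfill -> forward-discard ->
## mark-unknown, the only order whose fixpoint satisfies all three
## statements simultaneously; the composed pipeline is idempotent.

new_cohort_matrix <- function(status, reason, filled, rounds, roster) {
  structure(list(status = status, reason = reason, filled = filled,
                 rounds = rounds, roster = roster),
            class = "cohort_matrix")
}

#' Build the nets-by-rounds status matrix
#'
#' Reorganises raw round observations into a matrix with one row per roster
#' net and one column per survey round. Unobserved (net, round) pairs —
#' households not visited that round — become UNSURVEYED. Terminal-cause
#' reason labels travel with the observation cell that carried them.
#'
#' @param roster Data frame with columns `net_id`, `household_id`, `brand`,
#'   `zone` (one row per distributed net; `net_id` unique).
#' @param observations Data frame with columns `net_id`, `round_months`,
#'   `status` (PRESENT / DISCARDED / NOT_FOUND) and optionally `reason`.
#' @param rounds Month offsets defining the columns; defaults to the sorted
#'   unique `round_months` in `observations`.
#' @return A `cohort_matrix` object (status matrix, reason matrix, fill-flag
#'   matrix, rounds, roster).
#' @seealso [clean_status_matrix()]
#' @export
build_status_matrix <- function(roster, observations, rounds = NULL) {
  for (col in c("net_id", "household_id", "brand", "zone"))
    if (!col %in% names(roster)) stop("roster lacks column ", col)
  for (col in c("net_id", "round_months", "status"))
    if (!col %in% names(observations)) stop("observations lack column ", col)
  if (anyDuplicated(roster$net_id))
    stop("duplicated net_id in roster: ",
         paste(unique(roster$net_id[duplicated(roster$net_id)]), collapse = ", "))
  orphans <- setdiff(observations$net_id, roster$net_id)
  if (length(orphans))
    stop("observations reference net IDs absent from roster: ",
         paste(unique(orphans), collapse = ", "))
  if (is.null(rounds)) rounds <- sort(unique(observations$round_months))
  bad_round <- setdiff(observations$round_months, rounds)
  if (length(bad_round))
    stop("observations use round(s) outside the configured set: ",
         paste(unique(bad_round), collapse = ", "))
  bad_status <- setdiff(observations$status, c("PRESENT", "DISCARDED", "NOT_FOUND"))
  if (length(bad_status))
    stop("invalid observation status value(s): ",
         paste(unique(bad_status), collapse = ", "))
  key <- paste(observations$net_id, observations$round_months)
  if (anyDuplicated(key))
    stop("duplicate (net, round) observations: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))

  K <- length(rounds)
  n <- nrow(roster)
  status <- matrix("UNSURVEYED", n, K,
                   dimnames = list(roster$net_id, paste0("m", rounds)))
  reason <- matrix(NA_character_, n, K, dimnames = dimnames(status))
  filled <- matrix(NA_character_, n, K, dimnames = dimnames(status))
  ri <- match(observations$net_id, roster$net_id)
  ci <- match(observations$round_months, rounds)
  status[cbind(ri, ci)] <- observations$status
  if ("reason" %in% names(observations))
    reason[cbind(ri, ci)] <- as.character(observations$reason)
  new_cohort_matrix(status, reason, filled, rounds, roster)
}

## report nets violating the absorbing-discard property: a PRESENT cell at or
## after the first DISCARDED cell
check_absorbing <- function(status) {
  K <- ncol(status)
  first_disc <- apply(status == "DISCARDED", 1, function(z) {
    w <- which(z); if (length(w)) w[1] else K + 1L
  })
  last_pres <- apply(status == "PRESENT", 1, function(z) {
    w <- which(z); if (length(w)) w[length(w)] else 0L
  })
  bad <- which(last_pres > first_disc)
  if (length(bad))
    stop("inconsistent trajectories (PRESENT after DISCARDED) for net(s): ",
         paste(rownames(status)[bad], collapse = ", "))
  invisible(list(first_disc = first_disc, last_pres = last_pres))
}

#' Monotone cleaning rules
#'
#' `backfill_presence()` turns every cell strictly before a PRESENT cell into
#' PRESENT (a net seen later must have been in the household earlier).
#' `forward_discard()` turns every cell after a DISCARDED cell into DISCARDED
#' (discard is absorbing). `mark_unknown()` turns NOT_FOUND cells that precede
#' a later DISCARDED cell into UNKNOWN — it cannot be decided from the data
#' whether the net was already destroyed at that round — for resolution by
#' [fit_net_survival()]'s data augmentation. `clean_status_matrix()` composes
#' the three in that order; the composition is idempotent.
#'
#' A PRESENT cell at or after a DISCARDED cell violates the absorbing state
#' and raises an error naming the offending nets; raw data conflicts are
#' surfaced, never silently repaired.
#'
#' @param m A `cohort_matrix`.
#' @return The modified `cohort_matrix`. Cells rewritten by a rule carry a
#'   flag (`"backfill"`, `"forward"`, `"unknown"`) in the `filled` matrix.
#' @examples
#' roster <- data.frame(net_id = "N1", household_id = "H1",
#'                      brand = "A", zone = "rural")
#' obs <- data.frame(net_id = "N1", round_months = c(12, 24),
#'                   status = c("NOT_FOUND", "DISCARDED"),
#'                   reason = c(NA, "damaged_discarded"))
#' m <- build_status_matrix(roster, obs, rounds = c(6, 12, 24, 36))
#' clean_status_matrix(m)$status
#' @export
clean_status_matrix <- function(m) {
  mark_unknown(forward_discard(backfill_presence(m)))
}

#' @rdname clean_status_matrix
#' @export
backfill_presence <- function(m) {
  stopifnot(inherits(m, "cohort_matrix"))
  check_absorbing(m$status)
  st <- m$status
  K <- ncol(st)
  last_pres <- apply(st == "PRESENT", 1, function(z) {
    w <- which(z); if (length(w)) w[length(w)] else 0L
  })
  for (i in which(last_pres > 1)) {
    before <- seq_len(last_pres[i] - 1L)
    changed <- st[i, before] != "PRESENT"
    st[i, before] <- "PRESENT"
    m$filled[i, before][changed] <- "backfill"
    m$reason[i, before][changed] <- NA_character_
  }
  m$status <- st
  m
}

#' @rdname clean_status_matrix
#' @export
forward_discard <- function(m) {
  stopifnot(inherits(m, "cohort_matrix"))
  check_absorbing(m$status)
  st <- m$status
  K <- ncol(st)
  first_disc <- apply(st == "DISCARDED", 1, function(z) {
    w <- which(z); if (length(w)) w[1] else K + 1L
  })
  for (i in which(first_disc < K)) {
    after <- seq.int(first_disc[i] + 1L, K)
    changed <- st[i, after] != "DISCARDED"
    st[i, after] <- "DISCARDED"
    m$filled[i, after][changed] <- "forward"
  }
  m$status <- st
  m
}

#' @rdname clean_status_matrix
#' @export
mark_unknown <- function(m) {
  stopifnot(inherits(m, "cohort_matrix"))
  st <- m$status
  K <- ncol(st)
  first_disc <- apply(st == "DISCARDED", 1, function(z) {
    w <- which(z); if (length(w)) w[1] else K + 1L
  })
  for (i in which(first_disc <= K)) {
    before <- which(st[i, seq_len(first_disc[i] - 1L)] == "NOT_FOUND")
    if (length(before)) {
      st[i, before] <- "UNKNOWN"
      m$filled[i, before] <- "unknown"
    }
  }
  m$status <- st
  m
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("Cohort status matrix:", nrow(x$status), "nets x",
      ncol(x$status), "rounds (months ",
      paste(x$rounds, collapse = ", "), ")\n", sep = "")
  tab <- apply(x$status, 2, function(col) table(factor(col, STATUS_LEVELS)))
  print(tab)
  invisible(x)
}

#' @export
as.data.frame.cohort_matrix <- function(x, ...) {
  K <- length(x$rounds)
  n <- nrow(x$status)
  data.frame(net_id = rep(rownames(x$status), K),
             household_id = rep(x$roster$household_id, K),
             round_months = rep(x$rounds, each = n),
             status = as.vector(x$status),
             reason = as.vector(x$reason),
             filled = as.vector(x$filled),
             stringsAsFactors = FALSE)
}

#' Write a cleaned matrix as long-format delimited text
#'
#' One row per (net, round) with status, reason and fill flag.
#'
#' @param m A `cohort_matrix`.
#' @param path Output CSV path.
#' @export
write_status_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}
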