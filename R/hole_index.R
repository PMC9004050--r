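## Proportionate hole index (pHI) and WHO condition classes.
##
## Hole size classes (diameter): size 1: 0.5-2 cm, size 2: 2-10 cm,
## size 3: 10-25 cm, size 4: > 25 cm. The class weights approximate the
## damaged surface area contributed by a typical hole of that class, so the
## index is an area proxy in units of the smallest hole. Weights and
## thresholds are fixed constants of the WHO scheme, deliberately not
## configurable. Holes whose diameter falls exactly on a class boundary
## (2, 10 or 25 cm) are not assigned by the scheme; this package takes class
## counts as given and never re-derives them from diameters.

PHI_WEIGHTS <- c(size1 = 1, size2 = 23, size3 = 196, size4 = 576)

## Condition thresholds: Good 0-64, Damaged 65-642, Torn > 642.
## A net is serviceable while not Torn (pHI <= 642, i.e. destroyed surface
## below roughly 1000 cm^2).
PHI_GOOD_MAX        <- 64
PHI_SERVICEABLE_MAX <- 642

#' Proportionate hole index
#'
#' Computes the proportionate hole index (pHI), a weighted sum of hole counts
#' in four WHO diameter classes: \eqn{pHI = n_1 + 23 n_2 + 196 n_3 + 576 n_4}.
#' The weights approximate the relative damaged area of a typical hole in each
#' class, so pHI is an integer proxy for destroyed surface.
#'
#' @param size1,size2,size3,size4 Nonnegative integer counts of holes with
#'   diameter 0.5-2 cm, 2-10 cm, 10-25 cm and > 25 cm. Vectors are recycled
#'   by the usual rules.
#' @return Integer-valued numeric vector of pHI values.
#' @seealso [classify_condition()], [is_serviceable()]
#' @examples
#' compute_phi(1, 1, 1, 1)   # 796
#' compute_phi(64, 0, 0, 0)  # 64, boundary of Good
#' @export
compute_phi <- function(size1, size2, size3, size4) {
  counts <- cbind(size1, size2, size3, size4)
  if (anyNA(counts)) stop("hole counts must not be NA")
  if (any(counts < 0)) stop("hole counts must be nonnegative")
  if (any(counts != round(counts))) stop("hole counts must be whole numbers")
  as.numeric(counts %*% PHI_WEIGHTS)
}

#' Classify net condition from pHI
#'
#' Maps a pHI value to the WHO condition class: Good (pHI 0-64), Damaged
#' (65-642) or Torn (> 642). The three classes partition the nonnegative
#' integers.
#'
#' @param phi Nonnegative numeric vector of pHI values.
#' @return Factor with levels `GOOD`, `DAMAGED`, `TORN`.
#' @examples
#' classify_condition(c(0, 64, 65, 642, 643))
#' @export
classify_condition <- function(phi) {
  if (anyNA(phi) || any(phi < 0)) stop("phi must be nonnegative and non-NA")
  lab <- ifelse(phi <= PHI_GOOD_MAX, "GOOD",
                ifelse(phi <= PHI_SERVICEABLE_MAX, "DAMAGED", "TORN"))
  factor(lab, levels = c("GOOD", "DAMAGED", "TORN"))
}

#' Serviceability of a net
#'
#' A net is serviceable while its pHI does not exceed 642, i.e. while it is
#' not classified Torn.
#'
#' @inheritParams classify_condition
#' @return Logical vector.
#' @examples
#' is_serviceable(c(0, 642, 643))
#' @export
is_serviceable <- function(phi) {
  if (anyNA(phi) || any(phi < 0)) stop("phi must be nonnegative and non-NA")
  phi <= PHI_SERVICEABLE_MAX
}

#' pHI table from round observations
#'
#' Convenience wrapper computing pHI, condition class and serviceability for
#' every row of an observations table carrying the four hole-count columns
#' `holes1`..`holes4` (present nets only; rows for absent nets get NA).
#'
#' @param observations Data frame with columns `net_id`, `round_months`,
#'   `status` and `holes1`..`holes4`.
#' @return Data frame with columns `net_id`, `round_months`, `phi`,
#'   `condition`, `serviceable`.
#' @export
phi_table <- function(observations) {
  need <- c("net_id", "round_months", "status", paste0("holes", 1:4))
  miss <- setdiff(need, names(observations))
  if (length(miss)) stop("observations lack columns: ", paste(miss, collapse = ", "))
  present <- observations$status == "PRESENT"
  phi <- rep(NA_real_, nrow(observations))
  if (any(present)) {
    phi[present] <- compute_phi(observations$holes1[present],
                                observations$holes2[present],
                                observations$holes3[present],
                                observations$holes4[present])
  }
  out <- data.frame(net_id = observations$net_id,
                    round_months = observations$round_months,
                    phi = phi, stringsAsFactors = FALSE)
  out$condition <- factor(NA, levels = c("GOOD", "DAMAGED", "TORN"))
  out$condition[present] <- classify_condition(phi[present])
  out$serviceable <- ifelse(is.na(phi), NA, phi <= PHI_SERVICEABLE_MAX)
  out
}
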