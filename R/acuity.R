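#' Acuity transition parameters
#'
#' Sub-model linking postnatal hospital length of stay to the acuity mix
#' at discharge into the community. As mothers and babies move through the
#' postnatal ward their acuity tends to fall, so relatively few are
#' discharged with high acuity; the longer the stay, the further the mix
#' shifts toward the lower-acuity categories. The functional form is an
#' adjacent-category exponential transfer: each category's mass flows to
#' the next lower acuity category at a constant per-hour rate, with the
#' lowest category absorbing. Rates are fully user-configurable and the
#' sub-model is optional — scoring and costing run without it.
#'
#' @param category category ids, ordered from lowest to highest acuity.
#' @param decay_rate per-hour transfer rate toward the next lower acuity
#'   category, >= 0. The lowest-acuity category has no lower neighbour and
#'   must have rate 0.
#' @return A data frame with columns `category`, `decay_rate`.
#' @export
transition_params <- function(category, decay_rate) {
  d <- data.frame(category = as.character(category),
                  decay_rate = as.numeric(decay_rate),
                  stringsAsFactors = FALSE)
  stop_on_violations(validate_transition(d))
  d
}

validate_transition <- function(transition) {
  v <- no_violations()
  need <- c("category", "decay_rate")
  if (!all(need %in% names(transition))) {
    return(violation("transition", paste0(
      "missing column(s): ", paste(setdiff(need, names(transition)), collapse = ", "))))
  }
  if (anyDuplicated(transition$category)) {
    v <- bind_violations(v, violation("transition", "duplicate category"))
  }
  if (any(!is.finite(transition$decay_rate)) || any(transition$decay_rate < 0)) {
    v <- bind_violations(v, violation("transition", "decay_rate must be >= 0"))
  }
  if (nrow(transition) && is.finite(transition$decay_rate[1]) &&
      transition$decay_rate[1] != 0) {
    v <- bind_violations(v, violation("transition", paste0(
      "lowest-acuity category '", transition$category[1],
      "' must have decay_rate 0 (no lower category to transfer to)")))
  }
  v
}

validate_mix <- function(mix, tol = 1e-9) {
  if (!is.numeric(mix) || is.null(names(mix))) {
    validation_error("acuity mix must be a named numeric vector")
  }
  if (any(!is.finite(mix)) || any(mix < 0)) {
    validation_error("acuity mix proportions must be >= 0")
  }
  if (abs(sum(mix) - 1) > tol) {
    validation_error("acuity mix must sum to 1 (got ", format(sum(mix)), ")")
  }
  invisible(mix)
}

#' Acuity mix at discharge after a given hospital stay
#'
#' Propagates an admission acuity mix through the adjacent-category
#' transfer model for `stay_hours` hours. The dynamics are the linear
#' system `dp/dt = A p` with `A[k, k] = -r_k` and `A[k-1, k] = r_k`
#' (categories ordered lowest acuity first, rates `r` from `params`),
#' solved in closed form with the matrix exponential. The output is a
#' valid mix: it sums to 1, is never higher in acuity than the admission
#' mix (mass only moves downward), a zero-hour stay returns the admission
#' mix unchanged, and as the stay grows all mass collects in the
#' lowest-acuity category.
#'
#' @param admission_mix named numeric vector of proportions summing to 1,
#'   names ordered from lowest to highest acuity.
#' @param stay_hours hospital stay in hours (>= 0).
#' @param params a [transition_params()] table covering every category in
#'   `admission_mix`.
#' @return A named numeric vector: the discharge mix, same order as
#'   `admission_mix`.
#' @examples
#' p0 <- c("0a" = 0.4, "0b" = 0.3, "1" = 0.2, "2&3" = 0.1)
#' tp <- transition_params(names(p0), c(0, 0.01, 0.02, 0.03))
#' discharge_mix(p0, 48, tp)
#' @importFrom Matrix expm
#' @export
discharge_mix <- function(admission_mix, stay_hours, params) {
  validate_mix(admission_mix)
  if (!is_num_scalar(stay_hours) || stay_hours < 0) {
    validation_error("stay_hours must be a single value >= 0")
  }
  stop_on_violations(validate_transition(params))
  ids <- names(admission_mix)
  miss <- setdiff(ids, params$category)
  if (length(miss)) {
    config_error("no transition rate for category '",
                 paste(miss, collapse = "', '"), "'")
  }
  r <- params$decay_rate[match(ids, params$category)]
  if (r[1] != 0) {
    validation_error("lowest-acuity category '", ids[1],
                     "' must have decay_rate 0")
  }
  k <- length(ids)
  A <- matrix(0, k, k)
  diag(A) <- -r
  if (k > 1L) A[cbind(seq_len(k - 1L), seq_len(k - 1L) + 1L)] <- r[-1L]
  p <- as.numeric(Matrix::expm(A * stay_hours) %*% admission_mix)
  p[p < 0] <- 0            # clip tiny negative round-off
  p <- p / sum(p)
  names(p) <- ids
  p
}

#' Community demand after acuity transition
#'
#' Redistributes the annual demand across categories according to the
#' discharge acuity mix implied by the option's hospital stays. The
#' admission mix is taken from the categories' annual births; the stay
#' applied is the demand-weighted mean stay across categories (the
#' sub-model operates at the whole-service planning level). Used by
#' [annual_cost()] when transition parameters are supplied.
#'
#' @param option a [service_option()].
#' @param categories a [care_categories()] table, rows ordered lowest
#'   acuity first.
#' @param transition a [transition_params()] table.
#' @return Numeric vector of community annual demand, one per category in
#'   `categories` order; sums to the total annual births.
#' @export
community_demand <- function(option, categories, transition) {
  births <- setNames(categories$annual_births, categories$id)
  total <- sum(births)
  if (total == 0) return(births)
  p0 <- births / total
  stays <- vapply(categories$id, function(id)
    option$stages[[id]]$hospital$length_of_stay_hours, numeric(1))
  mean_stay <- sum(p0 * stays)
  total * discharge_mix(p0, mean_stay, transition)
}
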