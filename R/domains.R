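#' Quality domains and their weights
#'
#' The model scores every service option against the five Institute of
#' Medicine quality domains, interpreted for postnatal care: `safe`
#' (avoidance of care-associated harms, consistent care), `effective`
#' (supporting recovery, wellbeing and confidence in parenting), `timely`
#' (information at the appropriate stage, e.g. early infant-feeding advice),
#' `equitable` (equal access regardless of ability or geography) and
#' `person_centred` (individual care plans around mothers' preferences).
#'
#' `quality_domains()` returns the five domain ids in canonical order.
#' `default_domain_weights()` returns the consensus weight set elicited from
#' stakeholder workshops: safety 0.50, effectiveness 0.30, timeliness 0.05,
#' equity 0.05, person-centredness 0.10.
#'
#' @return `quality_domains()`: a character vector of length 5.
#'   `default_domain_weights()`: a named numeric vector summing to 1.
#' @examples
#' quality_domains()
#' default_domain_weights()
#' @export
quality_domains <- function() {
  c("safe", "effective", "timely", "equitable", "person_centred")
}

#' @rdname quality_domains
#' @export
default_domain_weights <- function() {
  c(safe = 0.50, effective = 0.30, timely = 0.05,
    equitable = 0.05, person_centred = 0.10)
}

#' Validate a domain weight vector
#'
#' Domain weights must be named, non-negative, and sum to 1 (within `tol`).
#'
#' @param weights named numeric vector of weights, one per quality domain.
#' @param tol absolute tolerance on the unit-sum constraint.
#' @return A data frame of violations (`where`, `problem`); zero rows if the
#'   weights are valid.
#' @seealso [renormalize_weights()]
#' @export
validate_weights <- function(weights, tol = 1e-9) {
  v <- no_violations()
  if (!is.numeric(weights) || is.null(names(weights)) || any(names(weights) == "")) {
    return(violation("weights", "weights must be a named numeric vector"))
  }
  if (anyDuplicated(names(weights))) {
    v <- bind_violations(v, violation("weights", "duplicate domain names"))
  }
  if (any(!is.finite(weights))) {
    v <- bind_violations(v, violation("weights", "non-finite weight"))
  } else {
    if (any(weights < 0)) {
      v <- bind_violations(v, violation(
        "weights", paste0("negative weight for '",
                          paste(names(weights)[weights < 0], collapse = "', '"), "'")))
    }
    if (abs(sum(weights) - 1) > tol) {
      v <- bind_violations(v, violation(
        "weights", sprintf("weights sum to %.10g, not 1", sum(weights))))
    }
  }
  v
}

check_weights <- function(weights) {
  stop_on_violations(validate_weights(weights))
  invisible(weights)
}

#' Set one domain weight and renormalize the others proportionally
#'
#' Used by the weight sensitivity analysis: the target domain's weight is
#' set to `new_weight` and every other domain's weight is scaled by the
#' common factor `(1 - new_weight) / (1 - w_old)` so the vector still sums
#' to 1 while the ratios among the untouched domains are preserved.
#'
#' @param weights a valid domain weight vector (see [validate_weights()]).
#' @param domain the domain whose weight is set.
#' @param new_weight the new weight, in `[0, 1]`.
#' @return A named numeric weight vector summing to 1.
#' @examples
#' # raising the safety weight from 0.50 to 0.60 scales the rest by 0.8
#' renormalize_weights(default_domain_weights(), "safe", 0.6)
#' @export
renormalize_weights <- function(weights, domain, new_weight) {
  check_weights(weights)
  if (!domain %in% names(weights)) {
    config_error("unknown domain '", domain, "' in weight vector")
  }
  if (!is_num_scalar(new_weight) || new_weight < 0 || new_weight > 1) {
    validation_error("new_weight must be a single value in [0, 1], got ",
                     format(new_weight))
  }
  w_old <- weights[[domain]]
  if (new_weight == w_old) return(weights)
  if (abs(1 - w_old) < 1e-12) {
    if (new_weight == 1) return(weights)
    validation_error("cannot renormalize: domain '", domain,
                     "' holds all the weight, proportional split of the ",
                     "remainder is undefined")
  }
  out <- weights * (1 - new_weight) / (1 - w_old)
  out[[domain]] <- new_weight
  out
}
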