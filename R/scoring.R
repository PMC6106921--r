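#' Impact matrices
#'
#' The impact matrix `q(i, j)` summarises the modelled contribution of
#' design parameter `i` to quality domain `j`, distilled from evidence and
#' expert judgement. It plays the role of the performance matrix in other
#' MCDA applications, but per separate design parameter. Entries may be
#' negative where the evidence base records harms (for instance, earlier
#' discharge can harm safety unless skilled community care is provided),
#' provided each domain's column sum stays positive so the normalisation
#' denominator is well defined; with negative entries the usual 0-100
#' score bounds no longer hold and validation warns rather than errs.
#'
#' @param entries a numeric matrix (or object coercible to one) with
#'   parameter ids as row names and quality domain ids as column names.
#' @return A numeric matrix with dimnames set.
#' @seealso [score_domain()], [validate_impact()]
#' @export
impact_matrix <- function(entries) {
  m <- as.matrix(entries)
  storage.mode(m) <- "double"
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    config_error("impact matrix must carry parameter row names and domain column names")
  }
  m
}

#' Validate an impact matrix against the parameter specifications
#'
#' Checks that every row matches a declared design parameter and that every
#' domain column with any nonzero entry has a strictly positive sum (the
#' scoring denominator). Negative entries are permitted (modelled harms)
#' but trigger a warning because they void the 0-100 score bounds.
#'
#' @param impact an [impact_matrix()].
#' @param specs the design-parameter specification table.
#' @return A data frame of violations; zero rows iff valid.
#' @export
validate_impact <- function(impact, specs) {
  v <- no_violations()
  unknown <- setdiff(rownames(impact), specs$id)
  for (id in unknown) {
    v <- bind_violations(v, violation("impact", paste0(
      "row '", id, "' does not match any declared design parameter")))
  }
  for (j in colnames(impact)) {
    q <- impact[, j]
    if (any(q != 0) && sum(q) <= 0) {
      v <- bind_violations(v, violation("impact", paste0(
        "domain '", j, "' has non-positive column sum ", format(sum(q)))))
    }
  }
  if (any(impact < 0)) {
    warning("impact matrix contains negative entries (modelled harms); ",
            "quality scores are no longer bounded to [0, 100]",
            call. = FALSE)
  }
  v
}

ratio_xz <- function(values, specs, ids, cap) {
  miss <- setdiff(ids, names(values))
  if (length(miss)) {
    config_error("missing parameter value(s) for '",
                 paste(miss, collapse = "', '"), "'")
  }
  z <- specs$max_beneficial_value[match(ids, specs$id)]
  if (anyNA(z)) {
    config_error("parameter '", ids[is.na(z)][1],
                 "' has no specification (no z value)")
  }
  r <- as.numeric(values[ids]) / z
  if (cap) r <- pmin(r, 1)
  r
}

#' Score one quality domain for a set of parameter values
#'
#' The core linear scoring model. Each design parameter contributes in
#' proportion to its attainment ratio `x / z` (value over maximum
#' beneficial value), weighted by its impact `q(i, j)` on the domain, and
#' the result is normalised so that a service setting every parameter at
#' its maximum beneficial value scores 100:
#'
#' \deqn{s_j = \frac{100 \sum_i q(i,j)\, x_i / z_i}{\sum_i q(i,j)}}
#'
#' By default the attainment ratio is capped at 1 (`min(x/z, 1)`): `z` is a
#' *maximum beneficial* value, so provision beyond it earns no further
#' credit. Set `cap = FALSE` to explore the uncapped linear model.
#'
#' @param values named numeric vector of parameter values `x` for one care
#'   category (a row of [derive_parameter_values()]).
#' @param specs the design-parameter specification table (supplies `z`).
#' @param impact an [impact_matrix()].
#' @param domain the quality domain id to score.
#' @param cap cap attainment ratios at 1 (default `TRUE`).
#' @return The domain score `s_j` (100 = every parameter at its maximum
#'   beneficial value).
#' @examples
#' specs <- rbind(parameter_spec("a", "", "h", 2, "hospital", "stay_hours"),
#'                parameter_spec("b", "", "h", 4, "hospital", "staff_hours"))
#' q <- impact_matrix(matrix(c(2, 1), 2, 1, dimnames = list(c("a", "b"), "safe")))
#' score_domain(c(a = 1, b = 4), specs, q, "safe")  # 100*(2*0.5 + 1*1)/3
#' @export
score_domain <- function(values, specs, impact, domain, cap = TRUE) {
  if (!domain %in% colnames(impact)) {
    config_error("domain '", domain, "' not present in impact matrix")
  }
  q <- impact[, domain]
  denom <- sum(q)
  if (!is.finite(denom) || denom <= 0) {
    validation_error("impact column for domain '", domain,
                     "' has non-positive sum; scores are undefined")
  }
  r <- ratio_xz(values, specs, rownames(impact), cap)
  100 * sum(q * r) / denom
}

score_domains <- function(values, specs, impact, cap = TRUE) {
  vapply(colnames(impact),
         function(j) score_domain(values, specs, impact, j, cap = cap),
         numeric(1))
}

#' Aggregate domain scores with domain weights
#'
#' The weighted sum `sum_j w_j s_j` used to summarise an option's quality
#' in a single number; with weights on the unit simplex the aggregate lies
#' between the smallest and largest domain score.
#'
#' @param domain_scores named numeric vector of per-domain scores.
#' @param weights a valid domain weight vector ([validate_weights()]).
#' @return The aggregate quality score.
#' @examples
#' aggregate_score(c(safe = 80, effective = 60, timely = 40,
#'                   equitable = 40, person_centred = 70),
#'                 default_domain_weights())  # 69
#' @export
aggregate_score <- function(domain_scores, weights) {
  check_weights(weights)
  need <- names(weights)[weights > 0]
  miss <- setdiff(need, names(domain_scores))
  if (length(miss)) {
    validation_error("no score for weighted domain(s) '",
                     paste(miss, collapse = "', '"), "'")
  }
  sum(weights[need] * domain_scores[need])
}

#' Quality profile of a service option
#'
#' Scores every care category of an option against every quality domain of
#' the bundle's impact matrix and aggregates with the bundle's domain
#' weights. The service-level aggregate is the demand-weighted mean of the
#' per-category aggregates (weights proportional to annual births).
#'
#' @param option a [service_option()] or the name of an option in `bundle`.
#' @param bundle a [pram_bundle()].
#' @param weights optional weight vector overriding the bundle's.
#' @param cap cap attainment ratios at 1 (see [score_domain()]).
#' @return An object of class `pram_quality`: list with `scores` (matrix,
#'   category x domain), `aggregate` (named vector per category),
#'   `service_aggregate`, and the `weights` used.
#' @export
quality_profile <- function(option, bundle, weights = NULL, cap = TRUE) {
  option <- resolve_option(bundle, option)
  weights <- weights %||% bundle$weights
  check_weights(weights)
  x <- derive_parameter_values(option, bundle$specs)
  scores <- t(apply(x, 1L, score_domains, specs = bundle$specs,
                    impact = bundle$impact, cap = cap))
  colnames(scores) <- colnames(bundle$impact)
  agg <- apply(scores, 1L, aggregate_score, weights = weights)
  births <- bundle$categories$annual_births[
    match(rownames(scores), bundle$categories$id)]
  svc <- if (sum(births) > 0) sum(agg * births) / sum(births) else mean(agg)
  structure(list(option = option$name, scores = scores, aggregate = agg,
                 service_aggregate = svc, weights = weights, cap = cap),
            class = "pram_quality")
}

#' @export
print.pram_quality <- function(x, digits = 1, ...) {
  cat("Quality profile for option", x$option,
      if (!x$cap) "(uncapped attainment ratios)", "\n")
  m <- cbind(x$scores, aggregate = x$aggregate)
  print(round(m, digits))
  cat(sprintf("Service aggregate (demand-weighted): %.*f\n", digits,
              x$service_aggregate))
  invisible(x)
}
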