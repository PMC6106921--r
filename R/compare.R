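#' Classify a redesign on the health equity impact plane
#'
#' Places a quality change and a cost change in the equity impact plane:
#' `win_win` when quality rises and cost falls, `win_lose` when quality
#' rises at extra cost, `lose_win` when cost falls at the expense of
#' quality, `lose_lose` when both worsen. A zero change on either axis is
#' `neutral` — the plane's boundaries are not forced into a quadrant.
#'
#' @param quality_delta change in (aggregate) quality score, B minus A.
#' @param cost_delta change in cost, B minus A (negative = saving).
#' @return A character vector of quadrant labels (vectorised over inputs).
#' @examples
#' classify_equity(8, -5)   # "win_win"
#' classify_equity(-1, -5)  # "lose_win"
#' @export
classify_equity <- function(quality_delta, cost_delta) {
  if (any(!is.finite(quality_delta)) || any(!is.finite(cost_delta))) {
    validation_error("equity classification requires finite deltas")
  }
  n <- max(length(quality_delta), length(cost_delta))
  q <- rep_len(quality_delta, n)
  cst <- rep_len(cost_delta, n)
  out <- rep("neutral", n)
  out[q > 0 & cst < 0] <- "win_win"
  out[q > 0 & cst > 0] <- "win_lose"
  out[q < 0 & cst < 0] <- "lose_win"
  out[q < 0 & cst > 0] <- "lose_lose"
  out
}

#' Compare two service options
#'
#' Full option-versus-option appraisal: per-category domain-score deltas
#' (B minus A), aggregate quality deltas, per-case and annual cost deltas,
#' an equity-plane quadrant per category (aggregate quality delta vs
#' annual cost delta), and service-level totals with the percentage cost
#' saving. All deltas are recomputed from the scoring and costing models
#' at call time; nothing is cached.
#'
#' @param a,b [service_option()]s, or names of options in `bundle`.
#'   Conventionally A is the current provision and B the redesign.
#' @param bundle a [pram_bundle()] supplying categories, parameter specs,
#'   impact matrix, weights and unit costs.
#' @param weights optional weight vector overriding the bundle's.
#' @param cap cap attainment ratios at 1 (see [score_domain()]).
#' @param transition optional [transition_params()] passed to
#'   [annual_cost()]; `NULL` (default) costs community demand at the
#'   admission split.
#' @return An object of class `pram_comparison`: list with `per_category`
#'   (data frame of deltas and quadrants), `domain_deltas` (matrix),
#'   `service` (totals, percentage saving, quadrant), and the underlying
#'   `quality` and `costs` objects for both options.
#' @export
compare_options <- function(a, b, bundle, weights = NULL, cap = TRUE,
                            transition = NULL) {
  a <- resolve_option(bundle, a)
  b <- resolve_option(bundle, b)
  va <- validate_service(a, bundle$categories)
  vb <- validate_service(b, bundle$categories)
  stop_on_violations(bind_violations(va, vb))

  qa <- quality_profile(a, bundle, weights = weights, cap = cap)
  qb <- quality_profile(b, bundle, weights = weights, cap = cap)
  ids <- bundle$categories$id
  dscore <- qb$scores[ids, , drop = FALSE] - qa$scores[ids, , drop = FALSE]
  dagg <- qb$aggregate[ids] - qa$aggregate[ids]

  ca <- annual_cost(a, bundle$categories, bundle$costs, transition = transition)
  cb <- annual_cost(b, bundle$categories, bundle$costs, transition = transition)
  d_case <- cb$by_category$per_case - ca$by_category$per_case
  d_annual <- cb$by_category$annual - ca$by_category$annual

  per_cat <- data.frame(category = ids, stringsAsFactors = FALSE,
                        check.names = FALSE)
  for (j in colnames(dscore)) per_cat[[paste0("d_", j)]] <- dscore[, j]
  per_cat$aggregate_delta <- dagg
  per_cat$cost_per_case_delta <- d_case
  per_cat$annual_cost_delta <- d_annual
  per_cat$quadrant <- classify_equity(dagg, d_annual)

  pct_saving <- if (ca$total > 0) 100 * (ca$total - cb$total) / ca$total else NA_real_
  service <- list(
    annual_cost_a = ca$total,
    annual_cost_b = cb$total,
    annual_cost_delta = cb$total - ca$total,
    pct_saving = pct_saving,
    aggregate_a = qa$service_aggregate,
    aggregate_b = qb$service_aggregate,
    aggregate_delta = qb$service_aggregate - qa$service_aggregate,
    quadrant = classify_equity(qb$service_aggregate - qa$service_aggregate,
                               cb$total - ca$total))
  structure(list(a = a$name, b = b$name, per_category = per_cat,
                 domain_deltas = dscore, service = service,
                 quality = list(a = qa, b = qb),
                 costs = list(a = ca, b = cb)),
            class = "pram_comparison")
}

#' @export
print.pram_comparison <- function(x, digits = 2, ...) {
  cat(sprintf("Comparison of options %s (baseline) and %s (redesign)\n",
              x$a, x$b))
  d <- x$per_category
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, digits)
  print(d, row.names = FALSE)
  s <- x$service
  cat(sprintf("Service: aggregate quality %+.*f, annual cost %+.0f, %s\n",
              digits, s$aggregate_delta, s$annual_cost_delta, s$quadrant))
  if (!is.na(s$pct_saving)) {
    cat(sprintf("Annual cost saving: %.1f%%\n", s$pct_saving))
  }
  invisible(x)
}

#' @export
summary.pram_comparison <- function(object, ...) {
  s <- object$service
  cat("Option", object$a, "vs option", object$b, "\n")
  cat(sprintf("  annual cost: %.0f -> %.0f (saving %.1f%%)\n",
              s$annual_cost_a, s$annual_cost_b, s$pct_saving))
  cat(sprintf("  service aggregate quality: %.1f -> %.1f (%+.2f)\n",
              s$aggregate_a, s$aggregate_b, s$aggregate_delta))
  cat("  equity plane:", s$quadrant, "at service level;",
      paste0(object$per_category$category, ": ",
             object$per_category$quadrant, collapse = ", "), "\n")
  invisible(object)
}

#' Tabular report of per-domain scores for two options
#'
#' Long-format table of the per-category, per-domain scores of both
#' options (the grouped-bar shape used when presenting quality profiles to
#' stakeholders), and the cost-versus-aggregate-quality table.
#'
#' @param comparison a [compare_options()] result.
#' @return A data frame: `domain_score_table()` has columns `category`,
#'   `domain`, `A`, `B`, `delta`; `cost_quality_table()` has columns
#'   `category`, `option`, `annual_cost`, `aggregate_quality`.
#' @export
domain_score_table <- function(comparison) {
  sa <- comparison$quality$a$scores
  sb <- comparison$quality$b$scores
  out <- expand.grid(category = rownames(sa), domain = colnames(sa),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$A <- sa[cbind(out$category, out$domain)]
  out$B <- sb[cbind(out$category, out$domain)]
  out$delta <- out$B - out$A
  out[order(match(out$category, rownames(sa)), match(out$domain, colnames(sa))), ,
      drop = FALSE]
}

#' @rdname domain_score_table
#' @export
cost_quality_table <- function(comparison) {
  ca <- comparison$costs$a$by_category
  cb <- comparison$costs$b$by_category
  qa <- comparison$quality$a
  qb <- comparison$quality$b
  rbind(
    data.frame(category = ca$category, option = comparison$a,
               annual_cost = ca$annual,
               aggregate_quality = as.numeric(qa$aggregate[ca$category]),
               stringsAsFactors = FALSE),
    data.frame(category = cb$category, option = comparison$b,
               annual_cost = cb$annual,
               aggregate_quality = as.numeric(qb$aggregate[cb$category]),
               stringsAsFactors = FALSE))
}

#' Plot an option comparison
#'
#' `which = "domains"` draws grouped bars of per-domain scores for both
#' options, one panel per care category; `which = "cost_quality"` draws
#' annual cost against aggregate quality with an arrow from A to B per
#' category (movement up and left is a win-win).
#'
#' @param x a [compare_options()] result.
#' @param which `"domains"` or `"cost_quality"`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @importFrom graphics arrows axis barplot legend mtext par points text
#' @importFrom grDevices grey
#' @export
plot.pram_comparison <- function(x, which = c("domains", "cost_quality"), ...) {
  which <- match.arg(which)
  if (which == "domains") {
    cats <- rownames(x$quality$a$scores)
    old <- par(mfrow = c(ceiling(length(cats) / 2), 2), mar = c(6, 4, 2, 1))
    on.exit(par(old))
    for (id in cats) {
      h <- rbind(A = x$quality$a$scores[id, ], B = x$quality$b$scores[id, ])
      barplot(h, beside = TRUE, ylim = c(0, 100), las = 2,
              col = c(grey(0.75), grey(0.35)), main = paste("Category", id),
              ylab = "quality score")
    }
    legend("topright", fill = c(grey(0.75), grey(0.35)),
           legend = c(x$a, x$b), bty = "n")
  } else {
    tab <- cost_quality_table(x)
    plot(tab$annual_cost, tab$aggregate_quality, type = "n",
         xlab = "annual cost", ylab = "aggregate quality score")
    a <- tab[tab$option == x$a, ]
    b <- tab[tab$option == x$b, ]
    arrows(a$annual_cost, a$aggregate_quality,
           b$annual_cost, b$aggregate_quality, length = 0.08, col = grey(0.4))
    points(a$annual_cost, a$aggregate_quality, pch = 1)
    points(b$annual_cost, b$aggregate_quality, pch = 16)
    text(a$annual_cost, a$aggregate_quality, a$category, pos = 3, cex = 0.8)
  }
  invisible(x)
}
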