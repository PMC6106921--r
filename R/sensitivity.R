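#' Weight sensitivity sweep
#'
#' Deterministic sensitivity analysis of the domain weights. For each
#' requested (domain, delta) pair the domain's weight is moved by `delta`,
#' the remaining weights are renormalized proportionally so the vector
#' still sums to 1 ([renormalize_weights()]), and the full option
#' comparison is recomputed. The question of interest is whether the
#' improvement in aggregate quality of the redesign over the baseline
#' keeps its sign under every reasonable weighting — if so the conclusion
#' is robust to the weighting debate.
#'
#' Perturbations that would push a weight outside `[0, 1]` are skipped
#' with a warning rather than failing the sweep.
#'
#' @param a,b options (objects or names in `bundle`); A baseline, B
#'   redesign.
#' @param bundle a [pram_bundle()].
#' @param domains domains to perturb; default safety, effectiveness and
#'   person-centredness, the three most debated in practice.
#' @param deltas weight perturbations; default `c(-0.2, -0.1, 0.1, 0.2)`.
#' @param weights optional base weight vector overriding the bundle's.
#' @param cap cap attainment ratios at 1 (see [score_domain()]).
#' @return An object of class `pram_weight_sweep`: list with `rows` (one
#'   row per retained perturbation: domain, delta, the renormalized weight
#'   vector, and the aggregate quality delta per category), `baseline`
#'   (unperturbed aggregate deltas per category) and `robust` (named
#'   logical per category: sign of the aggregate delta unchanged across
#'   the baseline and every perturbation).
#' @examples
#' \donttest{
#' dir <- tempfile(); generate_fixture(dir, seed = 1)
#' bundle <- read_pram_bundle(dir)
#' weight_sweep("A", "B", bundle)
#' }
#' @export
weight_sweep <- function(a, b, bundle,
                         domains = c("safe", "effective", "person_centred"),
                         deltas = c(-0.2, -0.1, 0.1, 0.2),
                         weights = NULL, cap = TRUE) {
  base_w <- weights %||% bundle$weights
  check_weights(base_w)
  unknown <- setdiff(domains, names(base_w))
  if (length(unknown)) {
    config_error("unknown domain(s) '", paste(unknown, collapse = "', '"), "'")
  }
  base_cmp <- compare_options(a, b, bundle, weights = base_w, cap = cap)
  cats <- base_cmp$per_category$category
  baseline <- setNames(base_cmp$per_category$aggregate_delta, cats)

  rows <- NULL
  signs <- matrix(sign(baseline), nrow = 1,
                  dimnames = list(NULL, cats))
  for (dom in domains) {
    for (d in deltas) {
      nw <- base_w[[dom]] + d
      if (nw < 0 || nw > 1) {
        warning(sprintf("skipping perturbation %s %+g: weight %g outside [0, 1]",
                        dom, d, nw), call. = FALSE)
        next
      }
      w2 <- renormalize_weights(base_w, dom, nw)
      cmp <- compare_options(a, b, bundle, weights = w2, cap = cap)
      dd <- setNames(cmp$per_category$aggregate_delta,
                     cmp$per_category$category)[cats]
      row <- data.frame(domain = dom, delta = d, stringsAsFactors = FALSE)
      for (j in names(w2)) row[[paste0("w_", j)]] <- w2[[j]]
      for (id in cats) row[[id]] <- dd[[id]]
      rows <- rbind(rows, row)
      signs <- rbind(signs, sign(dd))
    }
  }
  rows <- rows %||% data.frame()
  if (nrow(rows)) row.names(rows) <- NULL
  robust <- apply(signs, 2L, function(s) length(unique(s)) == 1L)
  structure(list(a = base_cmp$a, b = base_cmp$b, rows = rows,
                 baseline = baseline, robust = robust,
                 base_weights = base_w),
            class = "pram_weight_sweep")
}

#' @export
print.pram_weight_sweep <- function(x, digits = 2, ...) {
  cat(sprintf("Weight sensitivity of aggregate quality delta (%s vs %s)\n",
              x$b, x$a))
  cat("Baseline deltas:",
      paste(sprintf("%s %+.*f", names(x$baseline), digits, x$baseline),
            collapse = ", "), "\n")
  if (nrow(x$rows)) {
    d <- x$rows
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], round, digits)
    print(d, row.names = FALSE)
  }
  cat("Robust (delta sign unchanged):",
      paste(sprintf("%s %s", names(x$robust), x$robust), collapse = ", "), "\n")
  invisible(x)
}

#' Plot a weight sweep
#'
#' Bars of the aggregate quality delta (redesign minus baseline) for each
#' retained weight perturbation, one panel per care category, with the
#' unperturbed delta as a reference line.
#'
#' @param x a [weight_sweep()] result.
#' @param ... unused.
#' @return `x`, invisibly.
#' @importFrom graphics abline barplot par
#' @export
plot.pram_weight_sweep <- function(x, ...) {
  cats <- names(x$baseline)
  old <- par(mfrow = c(ceiling(length(cats) / 2), 2), mar = c(7, 4, 2, 1))
  on.exit(par(old))
  lab <- sprintf("%s %+g", x$rows$domain, x$rows$delta)
  for (id in cats) {
    barplot(x$rows[[id]], names.arg = lab, las = 2,
            main = paste("Category", id),
            ylab = sprintf("aggregate delta (%s - %s)", x$b, x$a))
    abline(h = x$baseline[[id]], lty = 2)
    abline(h = 0)
  }
  invisible(x)
}

apply_parameter_value <- function(option, spec, value) {
  parts <- strsplit(spec$derivation, ":", fixed = TRUE)[[1]]
  base <- parts[1]
  qual <- if (length(parts) > 1L) parts[2] else NULL
  for (id in names(option$stages)) {
    h <- option$stages[[id]]$hospital
    cm <- option$stages[[id]]$community
    if (base == "stay_hours") {
      h$length_of_stay_hours <- value
    } else if (base == "staff_hours") {
      if (!is.null(qual)) {
        h$staff_hours[qual] <- value
      } else {
        tot <- sum(h$staff_hours)
        if (tot > 0) {
          h$staff_hours <- h$staff_hours * value / tot
        } else if (value > 0) {
          config_error("cannot sweep '", spec$id, "': category '", id,
                       "' has no staff hours to scale")
        }
      }
    } else if (base == "feeding_parenting_hours") {
      h$feeding_parenting_hours <- value
    } else if (base %in% c("contact_count", "contact_minutes")) {
      ct <- cm$contacts
      sel <- if (is.null(qual)) rep(TRUE, nrow(ct)) else ct$kind == qual
      col <- if (base == "contact_count") "n" else "duration_minutes"
      cur <- if (base == "contact_count") sum(ct$n[sel])
             else sum(ct$n[sel] * ct$duration_minutes[sel])
      if (cur > 0) {
        ct[[col]][sel] <- ct[[col]][sel] * value / cur
      } else if (value > 0) {
        config_error("cannot sweep '", spec$id, "': category '", id,
                     "' has no matching contacts to scale")
      }
      cm$contacts <- ct
    } else {
      config_error("parameter '", spec$id, "': unknown derivation rule '",
                   spec$derivation, "'")
    }
    option$stages[[id]]$hospital <- h
    option$stages[[id]]$community <- cm
  }
  option
}

#' One-way design-parameter sweep
#'
#' Sets one design parameter to each value of a grid — in every care
#' category, by adjusting the underlying pathway description (scaling
#' contact counts, durations or staff-hours proportionally where the
#' parameter is an aggregate) — and fully recomputes quality scores and
#' costs at each grid point. Rows are independent recomputations of a
#' modified copy of the option; the input option is never mutated.
#'
#' @param option a [service_option()] or an option name in `bundle`.
#' @param parameter a design parameter id declared in the bundle's specs.
#' @param grid numeric vector of parameter values (>= 0).
#' @param bundle a [pram_bundle()].
#' @param weights optional weight vector overriding the bundle's.
#' @param cap cap attainment ratios at 1 (see [score_domain()]).
#' @return A data frame with one row per (grid value, category): the
#'   realised parameter value, per-domain scores, aggregate, per-case and
#'   annual cost.
#' @export
parameter_sweep <- function(option, parameter, grid, bundle, weights = NULL,
                            cap = TRUE) {
  option <- resolve_option(bundle, option)
  k <- match(parameter, bundle$specs$id)
  if (is.na(k)) config_error("unknown design parameter '", parameter, "'")
  if (any(!is.finite(grid)) || any(grid < 0)) {
    validation_error("grid values must be finite and >= 0")
  }
  spec <- bundle$specs[k, , drop = FALSE]
  out <- NULL
  for (val in grid) {
    opt2 <- apply_parameter_value(option, spec, val)
    qp <- quality_profile(opt2, bundle, weights = weights, cap = cap)
    cc <- annual_cost(opt2, bundle$categories, bundle$costs)
    d <- data.frame(value = val, category = rownames(qp$scores),
                    stringsAsFactors = FALSE)
    for (j in colnames(qp$scores)) d[[j]] <- qp$scores[, j]
    d$aggregate <- as.numeric(qp$aggregate)
    d$cost_per_case <- cc$by_category$per_case[
      match(d$category, cc$by_category$category)]
    d$annual_cost <- cc$by_category$annual[
      match(d$category, cc$by_category$category)]
    out <- rbind(out, d)
  }
  row.names(out) <- NULL
  out
}
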