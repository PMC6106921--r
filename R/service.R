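#' Care categories
#'
#' A care category is a broad level of need (acuity) of a mother-and-baby
#' dyad at the service-planning level, with its annual demand. The default
#' model uses four: `0a`, `0b`, `1` and the merged `2&3` (categories 2 and
#' 3 are combined because of the very low numbers in category 3). The list
#' is user-extensible; other applications may add categories reflecting,
#' for example, particular cultural or social needs.
#'
#' Note: the published category definitions give identical wording for `0a`
#' and `0b` (almost certainly a typesetting slip); the default fixture
#' reproduces the wording as published rather than inventing a distinction.
#'
#' @param id character vector of category labels, unique.
#' @param description free-text definitions (recycled if length 1).
#' @param annual_births annual number of births in each category (>= 0).
#' @return A data frame with columns `id`, `description`, `annual_births`.
#' @export
care_categories <- function(id, annual_births, description = "") {
  d <- data.frame(id = as.character(id),
                  description = rep_len(as.character(description), length(id)),
                  annual_births = as.numeric(annual_births),
                  stringsAsFactors = FALSE)
  stop_on_violations(validate_categories(d))
  d
}

validate_categories <- function(categories) {
  v <- no_violations()
  need <- c("id", "description", "annual_births")
  if (!all(need %in% names(categories))) {
    return(violation("categories", paste0(
      "missing column(s): ", paste(setdiff(need, names(categories)), collapse = ", "))))
  }
  if (anyDuplicated(categories$id)) {
    v <- bind_violations(v, violation("categories", paste0(
      "duplicate category id '", categories$id[duplicated(categories$id)][1], "'")))
  }
  bad <- !is.finite(categories$annual_births) | categories$annual_births < 0
  if (any(bad)) {
    v <- bind_violations(v, violation(
      paste0("categories/", categories$id[bad]),
      "annual_births must be a non-negative number"))
  }
  v
}

#' Design parameter specifications
#'
#' A design parameter is a controllable service lever (hours of hospital
#' stay, ward staff-hours per case, number of home visits, ...). Each
#' carries a maximum beneficial value `z`: the level beyond which no
#' further quality benefit accrues, which anchors the normalisation of the
#' quality scores. The `derivation` rule states how the parameter's value
#' `x` is computed from a service option's stage descriptions; supported
#' rules are:
#'
#' * `stay_hours` — hospital length of stay in hours;
#' * `staff_hours` or `staff_hours:<grade>` — regular ward staff-hours per
#'   case, totalled or for one grade;
#' * `feeding_parenting_hours` — dedicated feeding/parenting support hours
#'   on the postnatal ward;
#' * `contact_count` or `contact_count:<kind>` — number of community
#'   contacts (kinds: `home_visit`, `clinic`, `phone`);
#' * `contact_minutes` or `contact_minutes:<kind>` — total face/phone time
#'   in minutes across community contacts (travel excluded).
#'
#' @param id unique parameter identifier.
#' @param label free-text description.
#' @param unit measurement unit (hours, visits, minutes, ...).
#' @param max_beneficial_value the value `z > 0` at which benefit saturates.
#' @param setting `"hospital"` or `"community"`.
#' @param derivation derivation rule (see Details).
#' @return A one-row data frame; rbind rows to build a full specification
#'   table.
#' @export
parameter_spec <- function(id, label, unit, max_beneficial_value, setting,
                           derivation) {
  data.frame(id = id, label = label, unit = unit,
             max_beneficial_value = max_beneficial_value,
             setting = setting, derivation = derivation,
             stringsAsFactors = FALSE)
}

validate_specs <- function(specs) {
  v <- no_violations()
  need <- c("id", "label", "unit", "max_beneficial_value", "setting", "derivation")
  if (!all(need %in% names(specs))) {
    return(violation("parameters", paste0(
      "missing column(s): ", paste(setdiff(need, names(specs)), collapse = ", "))))
  }
  if (anyDuplicated(specs$id)) {
    v <- bind_violations(v, violation("parameters", paste0(
      "duplicate parameter id '", specs$id[duplicated(specs$id)][1], "'")))
  }
  bad <- !is.finite(specs$max_beneficial_value) | specs$max_beneficial_value <= 0
  if (any(bad)) {
    v <- bind_violations(v, violation(
      paste0("parameters/", specs$id[bad]),
      "max_beneficial_value must be > 0"))
  }
  bad <- !specs$setting %in% c("hospital", "community")
  if (any(bad)) {
    v <- bind_violations(v, violation(
      paste0("parameters/", specs$id[bad]),
      "setting must be 'hospital' or 'community'"))
  }
  v
}

contact_kinds <- function() c("home_visit", "clinic", "phone")

#' Community contacts
#'
#' One or more identical contacts between a mother and NHS staff in the
#' community stage of the pathway. `clinic` and `phone` contacts carry no
#' travel time (the mother attends, or no one travels); travel applies to
#' `home_visit` contacts only and is costed at the visiting staff member's
#' hourly rate.
#'
#' @param kind `"home_visit"`, `"clinic"` or `"phone"`.
#' @param grade staff grade delivering the contact (e.g. `"midwife"`).
#' @param duration_minutes contact duration, minutes >= 0.
#' @param travel_minutes staff travel time, minutes >= 0; must be 0 for
#'   clinic and phone contacts.
#' @param n number of such contacts on the pathway (>= 0).
#' @return A one-row contact data frame.
#' @export
contact <- function(kind, grade, duration_minutes, travel_minutes = 0, n = 1) {
  data.frame(kind = kind, grade = grade,
             duration_minutes = as.numeric(duration_minutes),
             travel_minutes = as.numeric(travel_minutes),
             n = as.numeric(n), stringsAsFactors = FALSE)
}

empty_contacts <- function() {
  data.frame(kind = character(), grade = character(),
             duration_minutes = numeric(), travel_minutes = numeric(),
             n = numeric(), stringsAsFactors = FALSE)
}

#' Pathway stage descriptions
#'
#' `hospital_stage()` describes the in-patient part of a category's
#' pathway: length of stay (hours), regular ward staff-hours per case by
#' grade, and dedicated feeding/parenting support hours. `community_stage()`
#' describes the community part as a table of [contact()] rows.
#'
#' @param length_of_stay_hours postnatal ward stay in hours (>= 0). Stays
#'   are stored in hours throughout (typical current practice discharges
#'   most mothers within 48 h).
#' @param staff_hours named numeric vector: regular ward staff-hours per
#'   case by grade, all >= 0.
#' @param feeding_parenting_hours dedicated feeding/parenting support hours
#'   per case on the ward (>= 0), distinct from regular staffing.
#' @param contacts a contact table built from [contact()] rows (rbind), or
#'   `NULL` for no community contacts.
#' @return A list of class `pram_hospital_stage` / `pram_community_stage`.
#' @export
hospital_stage <- function(length_of_stay_hours, staff_hours = numeric(),
                           feeding_parenting_hours = 0) {
  structure(list(length_of_stay_hours = as.numeric(length_of_stay_hours),
                 staff_hours = staff_hours,
                 feeding_parenting_hours = as.numeric(feeding_parenting_hours)),
            class = "pram_hospital_stage")
}

#' @rdname hospital_stage
#' @export
community_stage <- function(contacts = NULL) {
  structure(list(contacts = contacts %||% empty_contacts()),
            class = "pram_community_stage")
}

#' Service options
#'
#' A service option is a complete specification of postnatal care provision
#' — one hospital stage and one community stage per care category. Two
#' options are typically compared: A, the current provision, and B, a
#' proposed redesigned service.
#'
#' @param name option label (e.g. `"A"`).
#' @param stages named list, one entry per category id, each a list with
#'   elements `hospital` ([hospital_stage()]) and `community`
#'   ([community_stage()]).
#' @return An object of class `pram_service_option`.
#' @seealso [validate_service()], [derive_parameter_values()]
#' @export
service_option <- function(name, stages) {
  structure(list(name = as.character(name), stages = stages),
            class = "pram_service_option")
}

#' @export
print.pram_service_option <- function(x, ...) {
  cat("Service option", x$name, "-", length(x$stages), "care categories:",
      paste(names(x$stages), collapse = ", "), "\n")
  for (id in names(x$stages)) {
    st <- x$stages[[id]]
    cat(sprintf("  %-4s stay %.1f h, ward staff %.1f h/case (+%.2f h feeding/parenting), %g community contact(s)\n",
                id, st$hospital$length_of_stay_hours,
                sum(st$hospital$staff_hours),
                st$hospital$feeding_parenting_hours,
                sum(st$community$contacts$n)))
  }
  invisible(x)
}

#' Validate a service option against the declared care categories
#'
#' Checks structural invariants: the option covers every declared category
#' exactly once and no others; stays, staff-hours, durations, travel times
#' and contact counts are non-negative; clinic and phone contacts carry no
#' travel time. Violations are returned as data, not raised as errors, so
#' a whole bundle can be reported in one pass.
#'
#' @param option a [service_option()].
#' @param categories a [care_categories()] table.
#' @return A data frame of violations (`where`, `problem`); zero rows iff
#'   the option is well-formed.
#' @export
validate_service <- function(option, categories) {
  v <- no_violations()
  who <- paste0("option ", option$name)
  missing_cat <- setdiff(categories$id, names(option$stages))
  for (id in missing_cat) {
    v <- bind_violations(v, violation(who, paste0("missing category '", id, "'")))
  }
  extra <- setdiff(names(option$stages), categories$id)
  for (id in extra) {
    v <- bind_violations(v, violation(who, paste0("undeclared category '", id, "'")))
  }
  if (anyDuplicated(names(option$stages))) {
    v <- bind_violations(v, violation(who, "duplicate category entries"))
  }
  for (id in names(option$stages)) {
    st <- option$stages[[id]]
    loc <- paste0(who, "/", id)
    h <- st$hospital
    if (!is_num_scalar(h$length_of_stay_hours) || h$length_of_stay_hours < 0) {
      v <- bind_violations(v, violation(loc, "length_of_stay_hours must be >= 0"))
    }
    if (length(h$staff_hours) && (is.null(names(h$staff_hours)) ||
                                  any(names(h$staff_hours) == ""))) {
      v <- bind_violations(v, violation(loc, "staff_hours must be named by grade"))
    }
    if (any(!is.finite(h$staff_hours)) || any(h$staff_hours < 0)) {
      v <- bind_violations(v, violation(loc, "staff_hours must be >= 0"))
    }
    if (!is_num_scalar(h$feeding_parenting_hours) || h$feeding_parenting_hours < 0) {
      v <- bind_violations(v, violation(loc, "feeding_parenting_hours must be >= 0"))
    }
    ct <- st$community$contacts
    if (nrow(ct)) {
      bad <- !ct$kind %in% contact_kinds()
      if (any(bad)) {
        v <- bind_violations(v, violation(loc, paste0(
          "unknown contact kind '", ct$kind[bad][1], "'")))
      }
      if (any(ct$duration_minutes < 0) || any(!is.finite(ct$duration_minutes))) {
        v <- bind_violations(v, violation(loc, "contact duration_minutes must be >= 0"))
      }
      if (any(ct$travel_minutes < 0) || any(!is.finite(ct$travel_minutes))) {
        v <- bind_violations(v, violation(loc, "contact travel_minutes must be >= 0"))
      }
      if (any(ct$n < 0) || any(!is.finite(ct$n))) {
        v <- bind_violations(v, violation(loc, "contact count n must be >= 0"))
      }
      zt <- ct$kind %in% c("clinic", "phone") & ct$travel_minutes != 0
      if (any(zt)) {
        v <- bind_violations(v, violation(loc, paste0(
          ct$kind[zt][1], " contacts must have travel_minutes 0")))
      }
    }
  }
  v
}

derive_one <- function(stage, rule, spec_id) {
  parts <- strsplit(rule, ":", fixed = TRUE)[[1]]
  base <- parts[1]
  qual <- if (length(parts) > 1L) parts[2] else NULL
  h <- stage$hospital
  ct <- stage$community$contacts
  if (!is.null(qual) && base %in% c("contact_count", "contact_minutes")) {
    if (!qual %in% contact_kinds()) {
      config_error("parameter '", spec_id, "': unknown contact kind '", qual,
                   "' in derivation rule '", rule, "'")
    }
    ct <- ct[ct$kind == qual, , drop = FALSE]
  }
  switch(base,
    stay_hours = h$length_of_stay_hours,
    staff_hours = if (is.null(qual)) sum(h$staff_hours)
                  else sum(h$staff_hours[names(h$staff_hours) == qual]),
    feeding_parenting_hours = h$feeding_parenting_hours,
    contact_count = sum(ct$n),
    contact_minutes = sum(ct$n * ct$duration_minutes),
    config_error("parameter '", spec_id, "': unknown derivation rule '",
                 rule, "'")
  )
}

#' Derive design-parameter values from a service option
#'
#' Maps the structured pathway description onto the flat vector of design
#' parameter values `x` that the quality-scoring equation consumes, one
#' value per parameter per care category, following each specification's
#' `derivation` rule (see [parameter_spec()]). The mapping is pure and
#' deterministic: repeated calls on the same option return equal values.
#'
#' @param option a [service_option()].
#' @param specs a design-parameter specification table.
#' @return A numeric matrix, categories in rows and parameter ids in
#'   columns.
#' @examples
#' sp <- parameter_spec("hv", "home visits", "visits", 5, "community",
#'                      "contact_count:home_visit")
#' opt <- service_option("A", list(
#'   "0a" = list(hospital = hospital_stage(24, c(midwife = 2)),
#'               community = community_stage(contact("home_visit", "midwife", 40, 20, n = 3)))))
#' derive_parameter_values(opt, sp)
#' @export
derive_parameter_values <- function(option, specs) {
  stop_on_violations(validate_specs(specs))
  cats <- names(option$stages)
  x <- matrix(NA_real_, nrow = length(cats), ncol = nrow(specs),
              dimnames = list(cats, specs$id))
  for (cat in cats) {
    for (k in seq_len(nrow(specs))) {
      x[cat, specs$id[k]] <- derive_one(option$stages[[cat]],
                                        specs$derivation[k], specs$id[k])
    }
  }
  x
}
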