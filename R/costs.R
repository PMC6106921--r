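#' Unit costs
#'
#' The cost model distinguishes the maternity service's staff cost from the
#' bed with its associated infrastructure cost: the evidence suggests
#' quality depends more on staff-hours input than on the bare length of
#' stay, so the two components are computed and reported separately.
#' Currency is abstract (unit-free); supply rates in whatever currency the
#' analysis uses.
#'
#' @param staff_rates named numeric vector: cost per staff-hour by grade.
#' @param bed_day_rate cost per occupied bed-day, bed plus associated
#'   infrastructure (>= 0).
#' @param clinic_overhead_per_contact facility overhead added to each
#'   clinic contact (>= 0).
#' @param feeding_parenting_grade the grade whose rate prices dedicated
#'   feeding/parenting support hours (default maternity care assistant).
#' @return An object of class `pram_unit_costs`.
#' @export
unit_costs <- function(staff_rates, bed_day_rate = 0,
                       clinic_overhead_per_contact = 0,
                       feeding_parenting_grade = "maternity_care_assistant") {
  structure(list(staff_rates = staff_rates,
                 bed_day_rate = as.numeric(bed_day_rate),
                 clinic_overhead_per_contact = as.numeric(clinic_overhead_per_contact),
                 feeding_parenting_grade = feeding_parenting_grade),
            class = "pram_unit_costs")
}

validate_costs <- function(costs) {
  v <- no_violations()
  r <- costs$staff_rates
  if (length(r) && (is.null(names(r)) || any(names(r) == ""))) {
    v <- bind_violations(v, violation("unit_costs", "staff rates must be named by grade"))
  }
  if (any(!is.finite(r)) || any(r < 0)) {
    v <- bind_violations(v, violation("unit_costs", "staff rates must be >= 0"))
  }
  if (!is_num_scalar(costs$bed_day_rate) || costs$bed_day_rate < 0) {
    v <- bind_violations(v, violation("unit_costs", "bed_day_rate must be >= 0"))
  }
  if (!is_num_scalar(costs$clinic_overhead_per_contact) ||
      costs$clinic_overhead_per_contact < 0) {
    v <- bind_violations(v, violation("unit_costs", "clinic_overhead_per_contact must be >= 0"))
  }
  v
}

rate_for <- function(costs, grade) {
  r <- costs$staff_rates[grade]
  if (anyNA(r)) {
    config_error("no staff rate for grade '",
                 paste(grade[is.na(r)], collapse = "', '"), "'")
  }
  as.numeric(r)
}

#' Hospital cost per case
#'
#' Splits the in-patient cost into its staff component (regular ward
#' staff-hours plus dedicated feeding/parenting hours, each at the grade's
#' hourly rate) and its bed/infrastructure component (stay in bed-days
#' times the bed-day rate).
#'
#' @param stage a [hospital_stage()].
#' @param costs a [unit_costs()] table.
#' @return Named numeric vector `c(staff = , bed = )`, cost per case.
#' @examples
#' hospital_cost_per_case(
#'   hospital_stage(48, c(midwife = 2, maternity_care_assistant = 1)),
#'   unit_costs(c(midwife = 40, maternity_care_assistant = 20), bed_day_rate = 300))
#' @export
hospital_cost_per_case <- function(stage, costs) {
  staff <- 0
  if (length(stage$staff_hours)) {
    staff <- sum(stage$staff_hours * rate_for(costs, names(stage$staff_hours)))
  }
  if (stage$feeding_parenting_hours > 0) {
    staff <- staff + stage$feeding_parenting_hours *
      rate_for(costs, costs$feeding_parenting_grade)
  }
  bed <- stage$length_of_stay_hours / 24 * costs$bed_day_rate
  c(staff = staff, bed = bed)
}

#' Community cost per case
#'
#' Sums the cost of the community contacts: staff time (contact duration
#' plus any travel) at the grade's hourly rate, plus the clinic overhead
#' for each clinic contact. Phone contacts are costed as staff time with
#' zero travel.
#'
#' @param stage a [community_stage()].
#' @param costs a [unit_costs()] table.
#' @return Community cost per case (scalar).
#' @export
community_cost_per_case <- function(stage, costs) {
  ct <- stage$contacts
  if (!nrow(ct)) return(0)
  staff_time <- (ct$duration_minutes + ct$travel_minutes) / 60 *
    rate_for(costs, ct$grade)
  overhead <- ifelse(ct$kind == "clinic", costs$clinic_overhead_per_contact, 0)
  sum(ct$n * (staff_time + overhead))
}

#' Annual cost breakdown of a service option
#'
#' Per-category per-case costs (hospital staff, hospital bed/infrastructure,
#' community) scaled by annual births, plus the service total. If
#' transition parameters are supplied, the community demand is redistributed
#' across categories according to the acuity mix at discharge implied by the
#' option's hospital stays (see [discharge_mix()]); hospital costs always
#' follow the admission (birth) demand.
#'
#' @param option a [service_option()].
#' @param categories a [care_categories()] table (supplies annual demand).
#' @param costs a [unit_costs()] table.
#' @param transition optional [transition_params()] table; `NULL` (default)
#'   leaves community demand at the admission split.
#' @return An object of class `pram_costs`: list with `by_category` (data
#'   frame of per-case components, demand and annual cost) and `total`
#'   (service annual total).
#' @export
annual_cost <- function(option, categories, costs, transition = NULL) {
  ids <- categories$id
  miss <- setdiff(ids, names(option$stages))
  if (length(miss)) {
    validation_error("option ", option$name, " missing category '",
                     paste(miss, collapse = "', '"), "'")
  }
  hosp <- t(vapply(ids, function(id)
    hospital_cost_per_case(option$stages[[id]]$hospital, costs), numeric(2)))
  comm <- vapply(ids, function(id)
    community_cost_per_case(option$stages[[id]]$community, costs), numeric(1))
  births <- categories$annual_births
  comm_births <- births
  if (!is.null(transition)) {
    comm_births <- community_demand(option, categories, transition)
  }
  annual <- births * (hosp[, "staff"] + hosp[, "bed"]) + comm_births * comm
  by_cat <- data.frame(
    category = ids,
    annual_births = births,
    community_births = comm_births,
    hospital_staff = hosp[, "staff"],
    hospital_bed = hosp[, "bed"],
    community = comm,
    per_case = hosp[, "staff"] + hosp[, "bed"] + comm,
    annual = annual,
    stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE)
  structure(list(option = option$name, by_category = by_cat,
                 total = sum(annual)),
            class = "pram_costs")
}

#' @export
print.pram_costs <- function(x, ...) {
  cat("Annual cost breakdown for option", x$option, "\n")
  d <- x$by_category
  out <- data.frame(category = d$category,
                    `staff/case` = round(d$hospital_staff, 2),
                    `bed/case` = round(d$hospital_bed, 2),
                    `community/case` = round(d$community, 2),
                    births = d$annual_births,
                    annual = round(d$annual),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  cat("Service annual total:", format(round(x$total), big.mark = ","), "\n")
  invisible(x)
}
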