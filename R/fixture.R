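fixture_category_ids <- function() c("0a", "0b", "1", "2&3")

fixture_categories <- function(births) {
  care_categories(
    id = fixture_category_ids(),
    annual_births = births,
    description = c(
      # the published definitions give identical wording for 0a and 0b
      # (almost certainly a typesetting slip); reproduced as published
      "Routine care plus parenting support for healthy mother and baby but lacking parenting/feeding skill or confidence.",
      "Routine care plus parenting support for healthy mother and baby but lacking parenting/feeding skill or confidence.",
      "Additional care for mother and/or baby with some medical; mental health and/or social needs.",
      "Additional care with liaison with other services to meet complex or serious health or social needs (categories 2 and 3 merged; very low numbers in 3)."))
}

fixture_specs <- function() {
  rbind(
    parameter_spec("stay_hours", "postnatal ward length of stay", "hours",
                   72, "hospital", "stay_hours"),
    parameter_spec("ward_staff_hours", "regular ward staff-hours per case",
                   "staff-hours", 10, "hospital", "staff_hours"),
    parameter_spec("fp_hospital_hours",
                   "dedicated feeding/parenting support on the ward",
                   "hours", 2, "hospital", "feeding_parenting_hours"),
    parameter_spec("home_visits", "community home visits", "visits",
                   5, "community", "contact_count:home_visit"),
    parameter_spec("clinic_contacts", "feeding and parenting clinic contacts",
                   "visits", 1, "community", "contact_count:clinic"),
    parameter_spec("community_minutes", "total community contact time",
                   "minutes", 300, "community", "contact_minutes"))
}

# Illustrative impact matrix. Magnitudes are synthetic (the calibrated
# matrix used in practice is elicited locally and is not public); the
# qualitative pattern encodes the evidence summaries: ward staffing and
# home visits carry the safety weight (early discharge is only safe with
# skilled community care behind it), feeding/parenting support and
# community contact time drive effectiveness and timeliness, home visits
# and clinics carry equity and person-centredness.
fixture_impact <- function() {
  m <- rbind(
    stay_hours        = c(2.0, 1.0, 0.50, 0.00, 0.25),
    ward_staff_hours  = c(3.0, 2.0, 1.00, 0.50, 1.00),
    fp_hospital_hours = c(0.5, 2.0, 1.50, 0.50, 1.00),
    home_visits       = c(3.0, 3.0, 1.00, 2.00, 2.00),
    clinic_contacts   = c(0.5, 1.5, 1.00, 0.50, 0.50),
    community_minutes = c(1.0, 2.0, 1.00, 1.00, 2.00))
  colnames(m) <- quality_domains()
  impact_matrix(m)
}

fixture_costs <- function() {
  unit_costs(
    staff_rates = c(midwife = 45, maternity_care_assistant = 25),
    bed_day_rate = 400,
    clinic_overhead_per_contact = 10,
    feeding_parenting_grade = "maternity_care_assistant")
}

fixture_transition <- function() {
  transition_params(fixture_category_ids(), c(0, 0.01, 0.02, 0.03))
}

ri <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

fixture_option_a <- function() {
  stays <- c(ri(18, 30), ri(24, 42), ri(42, 60), ri(60, 96))
  midwife <- round(runif(4, c(1.5, 2, 3, 5), c(3, 4, 6, 9)), 1)
  mca <- round(runif(4, c(1, 1, 2, 3), c(2, 3, 4, 6)), 1)
  visits <- c(ri(1, 2), ri(1, 3), ri(2, 4), ri(3, 5))
  ids <- fixture_category_ids()
  stages <- list()
  for (k in seq_along(ids)) {
    stages[[ids[k]]] <- list(
      hospital = hospital_stage(
        length_of_stay_hours = stays[k],
        staff_hours = c(midwife = midwife[k],
                        maternity_care_assistant = mca[k]),
        feeding_parenting_hours = 0.25),
      community = community_stage(rbind(
        contact("home_visit", "midwife", duration_minutes = 40,
                travel_minutes = 20, n = visits[k]),
        contact("phone", "midwife", duration_minutes = 10, n = 1))))
  }
  service_option("A", stages)
}

#' Derive the redesigned option B from a current-provision option A
#'
#' Applies exactly the four-item redesign package to a copy of option A:
#'
#' 1. hospital stay reduced by 20% in every category;
#' 2. regular ward staffing reduced by 10%, with dedicated feeding and
#'    parenting support hours on the ward increased;
#' 3. one extra home visit for every category, two extra for category
#'    `2&3`;
#' 4. one feeding and parenting support clinic contact added for every
#'    category (supplementing, not replacing, the home visits).
#'
#' Everything else is left identical to A.
#'
#' @param a the current-provision option.
#' @param extra_fp_hours added dedicated feeding/parenting hours per case.
#' @param clinic_grade,clinic_minutes grade and duration of the added
#'   clinic contact.
#' @return The redesigned [service_option()], named `"B"`.
#' @export
redesign_option_b <- function(a, extra_fp_hours = 0.5,
                              clinic_grade = "maternity_care_assistant",
                              clinic_minutes = 30) {
  stages <- a$stages
  for (id in names(stages)) {
    h <- stages[[id]]$hospital
    h$length_of_stay_hours <- 0.8 * h$length_of_stay_hours
    h$staff_hours <- 0.9 * h$staff_hours
    h$feeding_parenting_hours <- h$feeding_parenting_hours + extra_fp_hours
    stages[[id]]$hospital <- h
    ct <- stages[[id]]$community$contacts
    hv <- which(ct$kind == "home_visit")[1]
    extra <- if (id == "2&3") 2 else 1
    if (is.na(hv)) {
      ct <- rbind(ct, contact("home_visit", "midwife", 40, 20, n = extra))
    } else {
      ct$n[hv] <- ct$n[hv] + extra
    }
    ct <- rbind(ct, contact("clinic", clinic_grade, clinic_minutes, n = 1))
    stages[[id]]$community <- community_stage(ct)
  }
  service_option("B", stages)
}

#' Generate the demonstration fixture bundle
#'
#' Writes a complete, self-consistent bundle to `dir`: four care
#' categories (`0a`, `0b`, `1`, `2&3`), six design parameters with
#' maximum beneficial values, an illustrative impact matrix, the default
#' domain weights (safety 0.50, effectiveness 0.30, timeliness 0.05,
#' equity 0.05, person-centredness 0.10), round NHS-scale unit costs,
#' acuity transition rates, and two service options: A, an illustrative
#' current provision whose demand, stays, staffing and visit counts are
#' drawn from realistic UK-service ranges under `seed`, and B, derived
#' from A by exactly the four-item redesign package of
#' [redesign_option_b()]. Output is deterministic given `seed`: the same
#' seed always yields byte-identical files (the caller's RNG state is
#' restored on exit).
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed driving the illustrative baselines.
#' @return The generated [pram_bundle()], invisibly.
#' @examples
#' dir <- tempfile()
#' bundle <- generate_fixture(dir, seed = 1)
#' list.files(dir)
#' @export
generate_fixture <- function(dir, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  births <- c(ri(1500, 2500), ri(1000, 2000), ri(800, 1500), ri(150, 400))
  a <- fixture_option_a()
  b <- redesign_option_b(a)
  bundle <- pram_bundle(
    categories = fixture_categories(births),
    specs = fixture_specs(),
    impact = fixture_impact(),
    weights = default_domain_weights(),
    costs = fixture_costs(),
    options = list(A = a, B = b),
    transition = fixture_transition())
  write_pram_bundle(bundle, dir)
  invisible(bundle)
}
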