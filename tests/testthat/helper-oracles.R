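# Independent brute-force oracles, written as plain element-by-element
# loops so they share no code path with the package implementation.

oracle_score <- function(x, z, q, cap = TRUE) {
  num <- 0
  den <- 0
  for (i in seq_along(q)) {
    r <- x[[i]] / z[[i]]
    if (cap && r > 1) r <- 1
    num <- num + q[[i]] * r
    den <- den + q[[i]]
  }
  100 * num / den
}

oracle_aggregate <- function(scores, weights) {
  total <- 0
  for (j in names(weights)) total <- total + weights[[j]] * scores[[j]]
  total
}

oracle_hospital_cost <- function(stage, costs) {
  staff <- 0
  for (g in names(stage$staff_hours)) {
    staff <- staff + stage$staff_hours[[g]] * costs$staff_rates[[g]]
  }
  if (stage$feeding_parenting_hours > 0) {
    staff <- staff + stage$feeding_parenting_hours *
      costs$staff_rates[[costs$feeding_parenting_grade]]
  }
  bed <- stage$length_of_stay_hours / 24 * costs$bed_day_rate
  c(staff = staff, bed = bed)
}

oracle_community_cost <- function(stage, costs) {
  total <- 0
  ct <- stage$contacts
  for (k in seq_len(nrow(ct))) {
    per <- (ct$duration_minutes[k] + ct$travel_minutes[k]) / 60 *
      costs$staff_rates[[ct$grade[k]]]
    if (ct$kind[k] == "clinic") per <- per + costs$clinic_overhead_per_contact
    total <- total + ct$n[k] * per
  }
  total
}

oracle_annual_total <- function(option, categories, costs) {
  total <- 0
  for (k in seq_len(nrow(categories))) {
    id <- categories$id[k]
    hc <- oracle_hospital_cost(option$stages[[id]]$hospital, costs)
    cc <- oracle_community_cost(option$stages[[id]]$community, costs)
    total <- total + categories$annual_births[k] * (hc[["staff"]] + hc[["bed"]] + cc)
  }
  total
}

# discrete-step mass-transfer simulation of the acuity transition
# (categories ordered lowest acuity first; mass flows to the left)
oracle_step_mix <- function(p0, rates, stay_hours, dt = 0.1) {
  p <- as.numeric(p0)
  steps <- round(stay_hours / dt)
  for (s in seq_len(steps)) {
    moved <- rates * dt * p
    p <- p - moved
    p[seq_len(length(p) - 1L)] <- p[seq_len(length(p) - 1L)] + moved[-1L]
  }
  names(p) <- names(p0)
  p
}

# small in-code bundle for unit tests (two categories, three parameters)
tiny_specs <- function() {
  rbind(
    parameter_spec("stay", "stay", "hours", 48, "hospital", "stay_hours"),
    parameter_spec("staff", "ward staff", "staff-hours", 6, "hospital",
                   "staff_hours"),
    parameter_spec("visits", "home visits", "visits", 4, "community",
                   "contact_count:home_visit"))
}

tiny_impact <- function() {
  m <- rbind(stay   = c(2.0, 1.0, 0.5, 0.2, 0.3),
             staff  = c(3.0, 2.0, 1.0, 0.5, 1.0),
             visits = c(2.0, 3.0, 1.0, 1.5, 2.0))
  colnames(m) <- quality_domains()
  impact_matrix(m)
}

tiny_costs <- function() {
  unit_costs(c(midwife = 40, maternity_care_assistant = 20),
             bed_day_rate = 300, clinic_overhead_per_contact = 5)
}

tiny_stage <- function(stay, midwife, mca, fp = 0, visits = 0, clinic = 0) {
  ct <- NULL
  if (visits > 0) {
    ct <- rbind(ct, contact("home_visit", "midwife", 40, 20, n = visits))
  }
  if (clinic > 0) {
    ct <- rbind(ct, contact("clinic", "maternity_care_assistant", 30, n = clinic))
  }
  list(hospital = hospital_stage(stay, c(midwife = midwife,
                                         maternity_care_assistant = mca), fp),
       community = community_stage(ct))
}

tiny_bundle <- function() {
  cats <- care_categories(c("lo", "hi"), c(100, 50))
  a <- service_option("A", list(
    lo = tiny_stage(24, 2, 1, fp = 0.25, visits = 2),
    hi = tiny_stage(48, 4, 2, fp = 0.25, visits = 3)))
  b <- service_option("B", list(
    lo = tiny_stage(19.2, 1.8, 0.9, fp = 0.75, visits = 3, clinic = 1),
    hi = tiny_stage(38.4, 3.6, 1.8, fp = 0.75, visits = 4, clinic = 1)))
  pram_bundle(categories = cats, specs = tiny_specs(), impact = tiny_impact(),
              weights = default_domain_weights(), costs = tiny_costs(),
              options = list(A = a, B = b),
              transition = transition_params(c("lo", "hi"), c(0, 0.02)))
}

fixture_bundle <- local({
  cache <- NULL
  function(seed = 123) {
    if (is.null(cache)) cache <<- generate_fixture(tempfile("fx"), seed = seed)
    cache
  }
})

random_nonneg_impact <- function(n_par, n_dom = 5) {
  m <- matrix(runif(n_par * n_dom, 0.05, 3), n_par, n_dom,
              dimnames = list(paste0("p", seq_len(n_par)),
                              quality_domains()[seq_len(n_dom)]))
  impact_matrix(m)
}

random_specs <- function(n_par) {
  do.call(rbind, lapply(seq_len(n_par), function(k)
    parameter_spec(paste0("p", k), "", "u", runif(1, 0.5, 10),
                   "hospital", "stay_hours")))
}
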