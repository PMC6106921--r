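# Bundle file layout (all plain delimiter-separated text, '.' decimal,
# header rows, so workshop participants can inspect and edit every input):
#   categories.csv   id,description,annual_births
#   parameters.csv   id,label,unit,setting,max_beneficial_value,derivation
#   impact.csv       parameter_id,<one column per quality domain>
#   weights.csv      domain,weight
#   staff_rates.csv  grade,rate_per_hour
#   cost_config.csv  key,value   (bed_day_rate, clinic_overhead_per_contact,
#                                 feeding_parenting_grade)
#   option_<name>.csv  one per service option (see write_option)
#   transition.csv   category,decay_rate   (optional)

bundle_files <- function() {
  c("categories.csv", "parameters.csv", "impact.csv", "weights.csv",
    "staff_rates.csv", "cost_config.csv")
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) config_error("file not found: ", path)
  d <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) config_error("parse error in ", path, ": ",
                                     conditionMessage(e)))
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    config_error(path, " (line 1): missing column(s) ",
                 paste(miss, collapse = ", "))
  }
  d
}

option_canonical_table <- function(option) {
  rows <- NULL
  blank <- function(n) rep(NA_real_, n)
  for (id in names(option$stages)) {
    st <- option$stages[[id]]
    h <- st$hospital
    rows <- rbind(rows, data.frame(
      category = id, record = "stay", kind = NA_character_,
      grade = NA_character_, hours = h$length_of_stay_hours,
      duration_minutes = NA_real_, travel_minutes = NA_real_, n = NA_real_,
      stringsAsFactors = FALSE))
    for (g in names(h$staff_hours)) {
      rows <- rbind(rows, data.frame(
        category = id, record = "staff", kind = NA_character_, grade = g,
        hours = as.numeric(h$staff_hours[[g]]), duration_minutes = NA_real_,
        travel_minutes = NA_real_, n = NA_real_, stringsAsFactors = FALSE))
    }
    rows <- rbind(rows, data.frame(
      category = id, record = "feeding_parenting", kind = NA_character_,
      grade = NA_character_, hours = h$feeding_parenting_hours,
      duration_minutes = NA_real_, travel_minutes = NA_real_, n = NA_real_,
      stringsAsFactors = FALSE))
    ct <- st$community$contacts
    if (nrow(ct)) {
      rows <- rbind(rows, data.frame(
        category = id, record = "contact", kind = ct$kind, grade = ct$grade,
        hours = blank(nrow(ct)), duration_minutes = ct$duration_minutes,
        travel_minutes = ct$travel_minutes, n = ct$n,
        stringsAsFactors = FALSE))
    }
  }
  rows
}

#' Read and write service option files
#'
#' One delimiter-separated file per option, long format: one row per
#' pathway fact with columns `category`, `record` (`stay`, `staff`,
#' `feeding_parenting` or `contact`), `kind`, `grade`, `hours`,
#' `duration_minutes`, `travel_minutes`, `n`; fields not applicable to a
#' record type are left empty. `write_option()` emits a canonical row
#' order (categories as given, staff grades sorted, contacts in stored
#' order) so identical options always produce byte-identical files, and
#' `read_option()` restores the structure field-for-field.
#'
#' @param option a [service_option()].
#' @param path file path; for `read_option()` the option name defaults to
#'   the `option_<name>.csv` stem.
#' @param name optional option name override.
#' @return `read_option()`: a [service_option()]. `write_option()`: the
#'   path, invisibly.
#' @export
write_option <- function(option, path) {
  write.csv(option_canonical_table(option), path, row.names = FALSE,
            na = "", eol = "\n")
  invisible(path)
}

#' @rdname write_option
#' @export
read_option <- function(path, name = NULL) {
  d <- read_table_checked(path, c("category", "record", "kind", "grade",
                                  "hours", "duration_minutes",
                                  "travel_minutes", "n"))
  if (is.null(name)) {
    name <- sub("^option_", "", sub("\\.csv$", "", basename(path)))
  }
  stages <- list()
  for (id in unique(d$category)) {
    rows <- d[d$category == id, , drop = FALSE]
    stay <- rows$hours[rows$record == "stay"]
    if (length(stay) != 1L) {
      config_error(path, ": category '", id, "' needs exactly one stay record")
    }
    staff <- rows[rows$record == "staff", , drop = FALSE]
    sh <- setNames(as.numeric(staff$hours), staff$grade)
    fp <- rows$hours[rows$record == "feeding_parenting"]
    fp <- if (length(fp)) fp[1] else 0
    ct <- rows[rows$record == "contact", , drop = FALSE]
    contacts <- if (nrow(ct)) {
      data.frame(kind = ct$kind, grade = ct$grade,
                 duration_minutes = as.numeric(ct$duration_minutes),
                 travel_minutes = as.numeric(ct$travel_minutes),
                 n = as.numeric(ct$n), stringsAsFactors = FALSE)
    } else NULL
    stages[[id]] <- list(
      hospital = hospital_stage(as.numeric(stay), sh, as.numeric(fp)),
      community = community_stage(contacts))
  }
  service_option(name, stages)
}

#' Model bundles: assembling every input of an appraisal
#'
#' A bundle collects everything one appraisal needs — care categories,
#' design-parameter specifications, the impact matrix, domain weights,
#' unit costs, one or more service options, and (optionally) acuity
#' transition parameters — cross-validated as a whole.
#'
#' `pram_bundle()` builds a bundle from in-memory pieces;
#' `read_pram_bundle()` loads one from a directory of plain-text files
#' (see [generate_fixture()] for the layout); `write_pram_bundle()` writes
#' the same dialect back bit-reproducibly. `validate_bundle()` returns
#' *all* validation problems together as a data frame rather than
#' stopping at the first; `read_pram_bundle(check = TRUE)` raises them as
#' one aggregated error.
#'
#' @param categories a [care_categories()] table.
#' @param specs a design-parameter specification table ([parameter_spec()]).
#' @param impact an [impact_matrix()].
#' @param weights a named domain weight vector.
#' @param costs a [unit_costs()] object.
#' @param options named list of [service_option()]s.
#' @param transition optional [transition_params()] table.
#' @return A list of class `pram_bundle`.
#' @export
pram_bundle <- function(categories, specs, impact, weights, costs, options,
                        transition = NULL) {
  structure(list(categories = categories, specs = specs, impact = impact,
                 weights = weights, costs = costs, options = options,
                 transition = transition),
            class = "pram_bundle")
}

#' @rdname pram_bundle
#' @param bundle a `pram_bundle`.
#' @export
validate_bundle <- function(bundle) {
  v <- bind_violations(
    validate_categories(bundle$categories),
    validate_specs(bundle$specs),
    validate_impact(bundle$impact, bundle$specs),
    validate_weights(bundle$weights),
    validate_costs(bundle$costs))
  unknown_dom <- setdiff(names(bundle$weights), colnames(bundle$impact))
  for (dm in unknown_dom) {
    if (bundle$weights[[dm]] > 0) {
      v <- bind_violations(v, violation("weights", paste0(
        "weighted domain '", dm, "' has no impact-matrix column")))
    }
  }
  for (opt in bundle$options) {
    v <- bind_violations(v, validate_service(opt, bundle$categories))
    # every parameter must be derivable and every grade priced
    tryCatch({
      derive_parameter_values(opt, bundle$specs)
      annual_cost(opt, bundle$categories, bundle$costs)
    }, pram_error = function(e) {
      v <<- bind_violations(v, violation(paste0("option ", opt$name),
                                         conditionMessage(e)))
    })
  }
  if (!is.null(bundle$transition)) {
    v <- bind_violations(v, validate_transition(bundle$transition))
    miss <- setdiff(bundle$categories$id, bundle$transition$category)
    for (id in miss) {
      v <- bind_violations(v, violation("transition", paste0(
        "no decay_rate for category '", id, "'")))
    }
  }
  v
}

#' @rdname pram_bundle
#' @param dir directory holding the bundle files.
#' @param check raise an aggregated error if validation fails
#'   (default `TRUE`).
#' @export
read_pram_bundle <- function(dir, check = TRUE) {
  if (!dir.exists(dir)) config_error("bundle directory not found: ", dir)
  p <- function(f) file.path(dir, f)

  categories <- read_table_checked(p("categories.csv"),
                                   c("id", "description", "annual_births"))
  categories$id <- as.character(categories$id)
  categories$description <- as.character(categories$description)
  categories$description[is.na(categories$description)] <- ""
  specs <- read_table_checked(p("parameters.csv"),
                              c("id", "label", "unit", "setting",
                                "max_beneficial_value", "derivation"))
  imp <- read_table_checked(p("impact.csv"), "parameter_id")
  impact <- impact_matrix(`rownames<-`(
    as.matrix(imp[, setdiff(names(imp), "parameter_id"), drop = FALSE]),
    imp$parameter_id))
  wt <- read_table_checked(p("weights.csv"), c("domain", "weight"))
  weights <- setNames(as.numeric(wt$weight), wt$domain)
  sr <- read_table_checked(p("staff_rates.csv"), c("grade", "rate_per_hour"))
  cfg <- read_table_checked(p("cost_config.csv"), c("key", "value"))
  cfgv <- setNames(as.character(cfg$value), cfg$key)
  costs <- unit_costs(
    staff_rates = setNames(as.numeric(sr$rate_per_hour), sr$grade),
    bed_day_rate = as.numeric(cfgv["bed_day_rate"] %||% 0),
    clinic_overhead_per_contact = as.numeric(cfgv["clinic_overhead_per_contact"] %||% 0),
    feeding_parenting_grade = unname(
      cfgv["feeding_parenting_grade"] %||% "maternity_care_assistant"))
  if (anyNA(costs$bed_day_rate) || anyNA(costs$clinic_overhead_per_contact)) {
    config_error(p("cost_config.csv"), ": non-numeric rate value")
  }

  opt_files <- sort(list.files(dir, pattern = "^option_.*\\.csv$"))
  if (!length(opt_files)) config_error("no option_<name>.csv files in ", dir)
  options <- lapply(opt_files, function(f) read_option(p(f)))
  names(options) <- vapply(options, function(o) o$name, character(1))

  transition <- NULL
  if (file.exists(p("transition.csv"))) {
    tr <- read_table_checked(p("transition.csv"), c("category", "decay_rate"))
    transition <- data.frame(category = as.character(tr$category),
                             decay_rate = as.numeric(tr$decay_rate),
                             stringsAsFactors = FALSE)
  }

  bundle <- pram_bundle(categories, specs, impact, weights, costs, options,
                        transition)
  if (check) stop_on_violations(validate_bundle(bundle))
  bundle
}

#' @rdname pram_bundle
#' @export
write_pram_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  w <- function(d, f) write.csv(d, p(f), row.names = FALSE, eol = "\n",
                                na = "")
  w(bundle$categories, "categories.csv")
  w(bundle$specs, "parameters.csv")
  imp <- data.frame(parameter_id = rownames(bundle$impact),
                    bundle$impact, check.names = FALSE,
                    stringsAsFactors = FALSE)
  w(imp, "impact.csv")
  w(data.frame(domain = names(bundle$weights),
               weight = as.numeric(bundle$weights)), "weights.csv")
  w(data.frame(grade = names(bundle$costs$staff_rates),
               rate_per_hour = as.numeric(bundle$costs$staff_rates)),
    "staff_rates.csv")
  w(data.frame(key = c("bed_day_rate", "clinic_overhead_per_contact",
                       "feeding_parenting_grade"),
               value = c(format(bundle$costs$bed_day_rate),
                         format(bundle$costs$clinic_overhead_per_contact),
                         bundle$costs$feeding_parenting_grade)),
    "cost_config.csv")
  for (opt in bundle$options) {
    write_option(opt, p(paste0("option_", opt$name, ".csv")))
  }
  if (!is.null(bundle$transition)) w(bundle$transition, "transition.csv")
  invisible(dir)
}

#' @export
print.pram_bundle <- function(x, ...) {
  cat("pram model bundle\n")
  cat("  categories:", paste(x$categories$id, collapse = ", "),
      sprintf("(%s births/yr)", format(sum(x$categories$annual_births),
                                       big.mark = ",")), "\n")
  cat("  design parameters:", nrow(x$specs), "| quality domains:",
      ncol(x$impact), "\n")
  cat("  options:", paste(names(x$options), collapse = ", "), "\n")
  cat("  acuity transition sub-model:",
      if (is.null(x$transition)) "absent" else "present", "\n")
  invisible(x)
}

resolve_option <- function(bundle, option) {
  if (inherits(option, "pram_service_option")) return(option)
  if (is.character(option) && length(option) == 1L) {
    if (!option %in% names(bundle$options)) {
      config_error("no option named '", option, "' in bundle (have: ",
                   paste(names(bundle$options), collapse = ", "), ")")
    }
    return(bundle$options[[option]])
  }
  config_error("option must be a service option object or an option name")
}
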