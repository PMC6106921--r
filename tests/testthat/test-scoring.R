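two_param_setup <- function(q = c(2, 1), z = c(2, 4)) {
  specs <- rbind(parameter_spec("a", "", "u", z[1], "hospital", "stay_hours"),
                 parameter_spec("b", "", "u", z[2], "hospital", "staff_hours"))
  imp <- impact_matrix(matrix(q, 2, 1, dimnames = list(c("a", "b"), "safe")))
  list(specs = specs, imp = imp)
}

test_that("scores are normalised to 100 at maximum beneficial values and 0 at zero provision", {
  s <- two_param_setup()
  expect_equal(score_domain(c(a = 2, b = 4), s$specs, s$imp, "safe"), 100)
  expect_equal(score_domain(c(a = 0, b = 0), s$specs, s$imp, "safe"), 0)
})

test_that("scoring follows the weighted attainment-ratio formula, with capping at z", {
  s <- two_param_setup()
  # x/z = (0.5, 1.0), q = (2, 1): 100*(2*0.5 + 1*1)/3
  expect_equal(score_domain(c(a = 1, b = 4), s$specs, s$imp, "safe"),
               100 * (2 * 0.5 + 1) / 3)
  # over-provision earns no extra credit when capped...
  expect_equal(score_domain(c(a = 3, b = 4), s$specs, s$imp, "safe"), 100)
  # ...but the uncapped mode keeps the linear model going
  expect_equal(score_domain(c(a = 3, b = 4), s$specs, s$imp, "safe", cap = FALSE),
               100 * (2 * 1.5 + 1) / 3)
})

test_that("degenerate impact columns and missing values raise typed errors", {
  s <- two_param_setup(q = c(0, 0))
  expect_error(score_domain(c(a = 1, b = 1), s$specs, s$imp, "safe"),
               "non-positive", class = "pram_validation_error")
  s2 <- two_param_setup()
  expect_error(score_domain(c(a = 1), s2$specs, s2$imp, "safe"),
               "'b'", class = "pram_config_error")
  expect_error(score_domain(c(a = 1, b = 1), s2$specs, s2$imp, "shiny"),
               "shiny", class = "pram_config_error")
})

test_that("negative impact entries are tolerated with a warning while column sums stay positive", {
  specs <- two_param_setup()$specs
  imp <- impact_matrix(matrix(c(2, -0.5), 2, 1,
                              dimnames = list(c("a", "b"), "safe")))
  expect_warning(v <- validate_impact(imp, specs), "negative")
  expect_identical(nrow(v), 0L)
  bad <- impact_matrix(matrix(c(1, -2), 2, 1,
                              dimnames = list(c("a", "b"), "safe")))
  suppressWarnings(v <- validate_impact(bad, specs))
  expect_match(v$problem, "non-positive column sum")
})

test_that("scores are bounded, affine below the cap, and match the brute-force oracle", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(2:5, 1)
    specs <- random_specs(n)
    imp <- random_nonneg_impact(n)
    z <- specs$max_beneficial_value
    x <- setNames(runif(n, 0, 1.4) * z, specs$id)
    for (j in colnames(imp)) {
      got <- score_domain(x, specs, imp, j)
      expect_gte(got, 0)
      expect_lte(got, 100)
      expect_equal(got, oracle_score(x[rownames(imp)], z, imp[, j]),
                   tolerance = 1e-12)
    }
    # halving one below-cap parameter halves its contribution (affinity)
    k <- sample(n, 1)
    xa <- x; xa[k] <- 0.8 * z[k]
    xb <- x; xb[k] <- 0.4 * z[k]
    x0 <- x; x0[k] <- 0
    j <- sample(colnames(imp), 1)
    up_a <- score_domain(xa, specs, imp, j) - score_domain(x0, specs, imp, j)
    up_b <- score_domain(xb, specs, imp, j) - score_domain(x0, specs, imp, j)
    expect_equal(up_a, 2 * up_b, tolerance = 1e-9)
  }
})

test_that("aggregation is the weighted sum, convex and permutation-invariant", {
  w <- default_domain_weights()
  all100 <- setNames(rep(100, 5), names(w))
  expect_equal(aggregate_score(all100, w), 100)
  s <- c(safe = 80, effective = 60, timely = 40, equitable = 40,
         person_centred = 70)
  expect_equal(aggregate_score(s, w), 69.0)
  one <- setNames(c(1, 0, 0, 0, 0), names(w))
  expect_equal(aggregate_score(s, one), s[["safe"]])
  # permutation invariance and min/max bounds
  set.seed(7)
  for (rep in 1:20) {
    sc <- setNames(runif(5, 0, 100), names(w))
    perm <- sample(5)
    expect_equal(aggregate_score(sc, w), aggregate_score(sc[perm], w))
    expect_equal(aggregate_score(sc, w), oracle_aggregate(sc, w),
                 tolerance = 1e-12)
    expect_gte(aggregate_score(sc, w), min(sc))
    expect_lte(aggregate_score(sc, w), max(sc))
  }
  expect_error(aggregate_score(s[-1], w), "safe",
               class = "pram_validation_error")
  expect_error(aggregate_score(s, w * 0.9), class = "pram_validation_error")
})

test_that("weight renormalization preserves the simplex and untouched ratios", {
  w <- default_domain_weights()
  expect_equal(renormalize_weights(w, "safe", 0.6),
               c(safe = 0.6, effective = 0.24, timely = 0.04,
                 equitable = 0.04, person_centred = 0.08))
  expect_equal(renormalize_weights(w, "safe", 0.5), w)
  expect_equal(renormalize_weights(w, "safe", 1),
               c(safe = 1, effective = 0, timely = 0, equitable = 0,
                 person_centred = 0))
  set.seed(11)
  for (rep in 1:30) {
    raw <- runif(5)
    w0 <- setNames(raw / sum(raw), names(w))
    dom <- sample(names(w), 1)
    nw <- runif(1)
    w1 <- renormalize_weights(w0, dom, nw)
    expect_equal(sum(w1), 1, tolerance = 1e-9)
    expect_identical(nrow(validate_weights(w1)), 0L)
    others <- setdiff(names(w), dom)
    expect_equal(w1[others] / sum(w1[others]), w0[others] / sum(w0[others]),
                 tolerance = 1e-9)
  }
  degenerate <- c(safe = 1, effective = 0)
  expect_error(renormalize_weights(degenerate, "safe", 0.5), "undefined",
               class = "pram_validation_error")
  expect_error(renormalize_weights(w, "safe", 1.2),
               class = "pram_validation_error")
})

test_that("quality profiles score per category and aggregate by demand", {
  b <- tiny_bundle()
  qp <- quality_profile("A", b)
  x <- derive_parameter_values(b$options$A, b$specs)
  for (id in c("lo", "hi")) {
    for (j in quality_domains()) {
      expect_equal(qp$scores[id, j],
                   oracle_score(x[id, rownames(b$impact)],
                                b$specs$max_beneficial_value, b$impact[, j]),
                   tolerance = 1e-12)
    }
    expect_equal(qp$aggregate[[id]],
                 oracle_aggregate(qp$scores[id, ], b$weights),
                 tolerance = 1e-12)
  }
  expect_equal(qp$service_aggregate,
               (100 * qp$aggregate[["lo"]] + 50 * qp$aggregate[["hi"]]) / 150)
})
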