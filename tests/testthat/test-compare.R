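test_that("equity plane classification covers every sign combination", {
  expect_identical(classify_equity(8, -5), "win_win")
  expect_identical(classify_equity(8, 5), "win_lose")
  expect_identical(classify_equity(-1, -5), "lose_win")
  expect_identical(classify_equity(-1, 5), "lose_lose")
  expect_identical(classify_equity(0, 0), "neutral")
  expect_identical(classify_equity(0, -5), "neutral")
  expect_identical(classify_equity(8, 0), "neutral")
  expect_identical(classify_equity(c(1, -1), c(-1, -1)),
                   c("win_win", "lose_win"))
  expect_error(classify_equity(NA_real_, 1), class = "pram_validation_error")
})

test_that("an option compared with itself has zero deltas and neutral quadrants", {
  b <- tiny_bundle()
  cmp <- compare_options("A", "A", b)
  expect_true(all(cmp$domain_deltas == 0))
  expect_true(all(cmp$per_category$aggregate_delta == 0))
  expect_true(all(cmp$per_category$annual_cost_delta == 0))
  expect_true(all(cmp$per_category$quadrant == "neutral"))
  expect_equal(cmp$service$annual_cost_delta, 0)
  expect_equal(cmp$service$pct_saving, 0)
})

test_that("a single extra contact moves only the domains it impacts, at extra cost", {
  specs <- rbind(
    parameter_spec("stay", "", "hours", 48, "hospital", "stay_hours"),
    parameter_spec("visits", "", "visits", 6, "community",
                   "contact_count:home_visit"))
  # home visits impact 'effective' only; stay carries the other domains
  imp <- rbind(stay   = c(1, 0, 1, 1, 1),
               visits = c(0, 1, 0, 0, 0))
  colnames(imp) <- quality_domains()
  cats <- care_categories("c1", 100)
  mk <- function(nm, nvis) service_option(nm, list(c1 = list(
    hospital = hospital_stage(24, c(midwife = 2)),
    community = community_stage(contact("home_visit", "midwife", 40, 20,
                                        n = nvis)))))
  b <- pram_bundle(cats, specs, impact_matrix(imp), default_domain_weights(),
                   tiny_costs(), list(A = mk("A", 2), B = mk("B", 3)))
  cmp <- compare_options("A", "B", b)
  expect_gt(cmp$domain_deltas["c1", "effective"], 0)
  expect_equal(unname(cmp$domain_deltas["c1",
    c("safe", "timely", "equitable", "person_centred")]), rep(0, 4))
  expect_gt(cmp$per_category$cost_per_case_delta, 0)
  expect_identical(cmp$per_category$quadrant, "win_lose")
})

test_that("comparisons are antisymmetric and consistent with recomputation", {
  b <- fixture_bundle()
  ab <- compare_options("A", "B", b)
  ba <- compare_options("B", "A", b)
  expect_equal(ab$domain_deltas, -ba$domain_deltas, tolerance = 1e-12)
  expect_equal(ab$per_category$aggregate_delta,
               -ba$per_category$aggregate_delta, tolerance = 1e-12)
  expect_equal(ab$per_category$annual_cost_delta,
               -ba$per_category$annual_cost_delta, tolerance = 1e-9)

  # no cached drift: deltas equal independent recomputation from the
  # scoring and costing primitives
  xa <- derive_parameter_values(b$options$A, b$specs)
  xb <- derive_parameter_values(b$options$B, b$specs)
  for (id in b$categories$id) {
    dd <- vapply(quality_domains(), function(j)
      oracle_score(xb[id, rownames(b$impact)], b$specs$max_beneficial_value,
                   b$impact[, j]) -
      oracle_score(xa[id, rownames(b$impact)], b$specs$max_beneficial_value,
                   b$impact[, j]), numeric(1))
    expect_equal(ab$domain_deltas[id, ], dd, tolerance = 1e-12)
    expect_equal(ab$per_category$aggregate_delta[
      ab$per_category$category == id],
      oracle_aggregate(dd, b$weights), tolerance = 1e-12)
  }
  expect_equal(ab$service$annual_cost_delta,
               oracle_annual_total(b$options$B, b$categories, b$costs) -
                 oracle_annual_total(b$options$A, b$categories, b$costs),
               tolerance = 1e-9)
  expect_equal(ab$service$pct_saving,
               100 * -ab$service$annual_cost_delta /
                 oracle_annual_total(b$options$A, b$categories, b$costs),
               tolerance = 1e-9)
})

test_that("mismatched category sets fail comparison with a validation error", {
  b <- tiny_bundle()
  chopped <- b$options$B
  chopped$stages$hi <- NULL
  expect_error(compare_options(b$options$A, chopped, b), "hi",
               class = "pram_validation_error")
})

test_that("report tables carry the per-domain grouped shape and the cost-quality shape", {
  b <- fixture_bundle()
  cmp <- compare_options("A", "B", b)
  dst <- domain_score_table(cmp)
  expect_identical(nrow(dst), 4L * 5L)
  expect_named(dst, c("category", "domain", "A", "B", "delta"))
  expect_equal(dst$delta, dst$B - dst$A)
  cqt <- cost_quality_table(cmp)
  expect_identical(nrow(cqt), 8L)
  expect_setequal(unique(cqt$option), c("A", "B"))
  expect_equal(sum(cqt$annual_cost[cqt$option == "A"]),
               cmp$service$annual_cost_a)
})
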