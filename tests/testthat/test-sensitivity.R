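test_that("a renormalized weight shift reweights a fixed delta profile as hand-computed", {
  # domain deltas (safe +10, effective +6, timely +4, equitable +4,
  # person-centred +7): base weights give +7.9; shifting safety 0.5 -> 0.6
  # rescales the rest by 0.8 and gives +8.32
  d <- c(safe = 10, effective = 6, timely = 4, equitable = 4,
         person_centred = 7)
  w <- default_domain_weights()
  expect_equal(aggregate_score(d, w),
               0.5 * 10 + 0.3 * 6 + 0.05 * 4 + 0.05 * 4 + 0.1 * 7)
  w2 <- renormalize_weights(w, "safe", 0.6)
  expect_equal(aggregate_score(d, w2),
               0.6 * 10 + 0.24 * 6 + 0.04 * 4 + 0.04 * 4 + 0.08 * 7)
  # when every domain moves by the same amount, any weighting reports it
  flat <- setNames(rep(3.5, 5), names(w))
  for (dom in names(w)) {
    expect_equal(aggregate_score(flat, renormalize_weights(w, dom, 0.3)), 3.5)
  }
})

test_that("weight sweeps recompute per perturbation and a zero shift reproduces baseline", {
  b <- tiny_bundle()
  sw <- weight_sweep("A", "B", b, domains = c("safe", "effective"),
                     deltas = c(-0.1, 0, 0.1))
  expect_identical(nrow(sw$rows), 6L)
  # each emitted weight vector is a valid simplex point
  wcols <- paste0("w_", names(b$weights))
  for (k in seq_len(nrow(sw$rows))) {
    w <- setNames(as.numeric(sw$rows[k, wcols]), names(b$weights))
    expect_identical(nrow(validate_weights(w)), 0L)
  }
  # zero perturbation rows equal the unperturbed deltas exactly
  zero <- sw$rows[sw$rows$delta == 0, ]
  for (id in c("lo", "hi")) {
    expect_equal(unique(zero[[id]]), unname(sw$baseline[id]))
  }
  # recomputation oracle: each row equals a fresh comparison at its weights
  for (k in seq_len(nrow(sw$rows))) {
    w <- setNames(as.numeric(sw$rows[k, wcols]), names(b$weights))
    fresh <- compare_options("A", "B", b, weights = w)
    expect_equal(as.numeric(sw$rows[k, c("lo", "hi")]),
                 fresh$per_category$aggregate_delta, tolerance = 1e-12)
  }
})

test_that("out-of-range perturbations are skipped with a warning, not an error", {
  b <- tiny_bundle()
  expect_warning(
    sw <- weight_sweep("A", "B", b, domains = "timely", deltas = c(-0.2, 0.1)),
    "outside")
  expect_identical(nrow(sw$rows), 1L)
  expect_identical(sw$rows$delta, 0.1)
})

test_that("same-signed domain deltas make the verdict necessarily robust", {
  # convexity: the aggregate delta is a convex combination of the domain
  # deltas, so if those share one sign no weighting can flip it
  b <- fixture_bundle()
  cmp <- compare_options("A", "B", b)
  expect_true(all(cmp$domain_deltas > 0))
  sw <- suppressWarnings(weight_sweep("A", "B", b))
  expect_true(all(sw$robust))
  set.seed(19)
  for (rep in 1:5) {
    doms <- sample(names(b$weights), 2)
    sw2 <- suppressWarnings(weight_sweep("A", "B", b, domains = doms,
                                         deltas = runif(3, -0.04, 0.04)))
    expect_true(all(sw2$robust))
  }
})

test_that("one-way parameter sweeps recompute rows independently and monotonically", {
  b <- fixture_bundle()
  base_q <- quality_profile("A", b)
  base_c <- annual_cost(b$options$A, b$categories, b$costs)
  x0 <- derive_parameter_values(b$options$A, b$specs)

  # a grid containing only the current value reproduces the baseline; note
  # home-visit counts differ per category, so sweep a shared-value lever
  cur_fp <- unique(x0[, "fp_hospital_hours"])
  expect_length(cur_fp, 1L)
  row0 <- parameter_sweep("A", "fp_hospital_hours", cur_fp, b)
  expect_equal(setNames(row0$aggregate, row0$category), base_q$aggregate,
               tolerance = 1e-12)
  expect_equal(row0$annual_cost,
               base_c$by_category$annual[
                 match(row0$category, base_c$by_category$category)],
               tolerance = 1e-9)

  # monotone non-decreasing scores along an increasing grid (all q >= 0)
  grid <- c(0, 0.5, 1, 2)
  sweep <- parameter_sweep("A", "home_visits", grid, b)
  for (id in b$categories$id) {
    rows <- sweep[sweep$category == id, ]
    expect_true(all(diff(rows$aggregate) >= -1e-12))
    expect_true(all(diff(rows$annual_cost) >= -1e-9))
  }

  # rows match one-at-a-time recomputation with hand-modified options
  for (val in grid) {
    opt <- b$options$A
    for (id in names(opt$stages)) {
      ct <- opt$stages[[id]]$community$contacts
      hv <- ct$kind == "home_visit"
      ct$n[hv] <- ct$n[hv] * val / sum(ct$n[hv])
      opt$stages[[id]]$community$contacts <- ct
    }
    x <- derive_parameter_values(opt, b$specs)
    for (id in b$categories$id) {
      row <- sweep[sweep$category == id & sweep$value == val, ]
      for (j in quality_domains()) {
        expect_equal(row[[j]],
                     oracle_score(x[id, rownames(b$impact)],
                                  b$specs$max_beneficial_value, b$impact[, j]),
                     tolerance = 1e-12)
      }
    }
  }

  # the input option is never mutated by sweeping
  expect_equal(derive_parameter_values(b$options$A, b$specs), x0)
  expect_error(parameter_sweep("A", "nope", 1, b), "nope",
               class = "pram_config_error")
})
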