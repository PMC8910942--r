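test_that("rating-scale normalization divides by the weight sum", {
  ids <- core_ids(final_fw)
  uniform <- normalize_rating_scale(raw_weights("p1", stats::setNames(rep(5, 8), ids)))
  expect_equal(unname(uniform$weights), rep(0.125, 8))

  w <- stats::setNames(c(5, 5, 4, 4, 4, 4, 3, 3), ids)
  nw <- normalize_rating_scale(raw_weights("p1", w))
  expect_equal(unname(nw$weights),
               c(0.15625, 0.15625, 0.125, 0.125, 0.125, 0.125,
                 0.09375, 0.09375))
  expect_equal(sum(nw$weights), 1)
})

test_that("rating-scale normalization rejects out-of-range weights", {
  expect_error(raw_weights("p1", c(a = 0, b = 3)), "1\\.\\.5")
  expect_error(raw_weights("p1", c(a = 6, b = 3)), "1\\.\\.5")
  expect_error(normalize_rating_scale(c(a = 2.5, b = 3)), "1\\.\\.5")
})

test_that("normalized weights are scale invariant and monotone", {
  set.seed(11)
  for (i in 1:25) {
    w <- stats::setNames(sample(1:5, 8, replace = TRUE), letters[1:8])
    base <- normalize_rating_scale(w)$weights
    expect_equal(sum(base), 1, tolerance = 1e-12)
    k <- stats::runif(1, 0.1, 10)
    expect_equal(normalize_rating_scale(w * k, check_range = FALSE)$weights,
                 base)
    # raising one raw weight raises its share and lowers every other
    j <- sample(8, 1)
    w2 <- w
    w2[j] <- w2[j] + 1
    bumped <- normalize_rating_scale(w2, check_range = FALSE)$weights
    expect_gt(bumped[j], base[j])
    expect_true(all(bumped[-j] < base[-j]))
  }
})

test_that("point-allocation normalization multiplies by domain weight then rescales", {
  nw <- normalize_point_allocation(
    ratings = c(a = 1, b = 1, c = 1, d = 1),
    domain_weights = c(clinical = 0.6, economic = 0.4),
    domain_of = c(a = "clinical", b = "clinical",
                  c = "economic", d = "economic"))
  expect_equal(unname(nw$weights), c(0.3, 0.3, 0.2, 0.2))

  # one domain with weight 1 reduces to the uniform case
  one <- normalize_point_allocation(
    stats::setNames(rep(2, 8), letters[1:8]),
    c(all = 1), stats::setNames(rep("all", 8), letters[1:8]))
  expect_equal(unname(one$weights), rep(0.125, 8))

  expect_error(normalize_point_allocation(
    c(a = 1, b = 1), c(clinical = 1), c(a = "clinical", b = "economic")),
    "economic")
  expect_error(normalize_point_allocation(
    c(a = 0, b = 1), c(d = 1), c(a = "d", b = "d")), "positive")
})

test_that("weight aggregation reports mean and sample SD in descending order", {
  w <- data.frame(panellist_id = rep(c("p1", "p2", "p3"), each = 2),
                  criterion_id = rep(c("a", "b"), 3),
                  weight = c(5, 5, 4, 5, 5, 5))
  roster <- data.frame(panellist_id = c("p1", "p2", "p3"),
                       profile = c("clinician", "evaluator", "evaluator"))
  ws <- aggregate_weights(w, roster)
  a <- ws$overall[ws$overall$criterion_id == "a", ]
  expect_equal(round(a$mean, 2), 4.67)
  expect_equal(round(a$sd, 2), 0.58)  # sample SD, n - 1 denominator
  b <- ws$overall[ws$overall$criterion_id == "b", ]
  expect_equal(b$mean, 5)
  expect_equal(b$sd, 0)
  expect_equal(ws$overall$criterion_id, c("b", "a"))  # descending mean
  # a one-panellist stratum has no dispersion estimate
  expect_true(is.na(ws$by_profile$clinician$sd[1]))
  # population SD is available as an option
  pop <- aggregate_weights(w, roster, dispersion = "population")
  a_pop <- pop$overall[pop$overall$criterion_id == "a", ]
  expect_equal(a_pop$sd, sqrt(mean((c(5, 4, 5) - mean(c(5, 4, 5)))^2)))
})

test_that("weight aggregation is permutation invariant and validates the roster", {
  set.seed(3)
  w <- data.frame(panellist_id = rep(sprintf("p%d", 1:6), each = 3),
                  criterion_id = rep(c("a", "b", "c"), 6),
                  weight = sample(1:5, 18, replace = TRUE))
  roster <- data.frame(panellist_id = sprintf("p%d", 1:6),
                       profile = rep(c("evaluator", "clinician"), 3))
  ws1 <- aggregate_weights(w, roster)
  ws2 <- aggregate_weights(w[sample(nrow(w)), ], roster[sample(6), ])
  expect_equal(ws1$overall, ws2$overall)
  expect_equal(ws1$by_profile, ws2$by_profile)

  expect_error(aggregate_weights(w, roster[-1, ]), "unknown panellist")
  expect_error(aggregate_weights(w[0, ], roster), "empty panel")
})

test_that("panel composition reproduces printed profile percentages", {
  roster <- data.frame(
    panellist_id = sprintf("p%02d", 1:18),
    profile = rep(c("evaluator", "clinician", "policymaker",
                    "patient_representative"), c(7, 5, 5, 1)))
  comp <- panel_composition(roster)
  expect_equal(comp$percent[comp$profile == "evaluator"], 39)
  expect_equal(sum(comp$n), 18)
  expect_equal(sum(comp$fraction), 1)
})
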