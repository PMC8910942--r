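test_that("signed-rank test handles the textbook cases", {
  # identical assessments carry no information
  r0 <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(r0$no_information)
  expect_equal(r0$n_nonzero, 0)
  expect_equal(r0$p_value, 1)

  # five all-positive unit-spaced differences: p = 2/32
  r1 <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(r1$w_minus, 0)
  expect_equal(r1$w_plus, 15)
  expect_equal(r1$p_value, 2 / 32)
  expect_equal(r1$method, "exact")

  # symmetric +a/-a pairs: perfectly balanced
  r2 <- wilcoxon_signed_rank(c(3, 1), c(1, 3))
  expect_equal(r2$w_plus, r2$w_minus)
  expect_equal(r2$p_value, 1)

  expect_error(wilcoxon_signed_rank(1:3, 1:2), "length mismatch")
})

test_that("rank-sum identity and antisymmetry hold on random input", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(2:15, 1)
    x <- sample(0:5, n, replace = TRUE)
    y <- sample(0:5, n, replace = TRUE)
    if (all(x == y)) x[1] <- x[1] + 1
    a <- wilcoxon_signed_rank(x, y)
    expect_equal(a$w_plus + a$w_minus,
                 a$n_nonzero * (a$n_nonzero + 1) / 2)
    b <- wilcoxon_signed_rank(y, x)
    expect_equal(a$w_plus, b$w_minus)
    expect_equal(a$w_minus, b$w_plus)
    expect_equal(a$p_value, b$p_value)
    expect_gte(a$p_value, 0)
    expect_lte(a$p_value, 1)
  }
})

test_that("exact p agrees with stats::wilcox.test on tie-free data", {
  set.seed(37)
  for (i in 1:25) {
    n <- sample(4:15, 1)
    d <- sample(c(-1, 1), n, replace = TRUE) * sample(seq(n) + stats::runif(n), n)
    ref <- suppressWarnings(
      stats::wilcox.test(d, exact = TRUE, correct = FALSE))$p.value
    got <- wilcoxon_signed_rank(d, rep(0, n))$p_value
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("normal approximation matches the corrected large-sample test", {
  set.seed(41)
  for (i in 1:10) {
    n <- 30
    d <- sample(c(-1, 1), n, replace = TRUE) * (seq_len(n) + stats::runif(n))
    got <- wilcoxon_signed_rank(d, rep(0, n), exact_limit = 20)
    expect_equal(got$method, "normal_approximation")
    ref <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = TRUE))$p.value
    expect_equal(got$p_value, ref, tolerance = 1e-10)
  }
})

test_that("Pratt zero handling keeps zeros in the ranking", {
  x <- c(1, 2, 3, 4, 4)
  y <- c(1, 1, 1, 1, 1)
  a <- wilcoxon_signed_rank(x, y, zero_method = "discard")
  b <- wilcoxon_signed_rank(x, y, zero_method = "pratt")
  expect_equal(a$n_nonzero, b$n_nonzero)
  expect_gt(b$w_plus, a$w_plus)  # nonzero ranks shift up past the zero
  expect_gte(b$p_value, 0)
  expect_lte(b$p_value, 1)
})

test_that("identical test and re-test give a consistent verdict", {
  spec <- panel_spec(seed = 9)
  a <- simulate_assessment(spec)
  b <- simulate_retest(spec, a)
  wl <- norm_weight_list(simulate_weights(spec)$weights)
  cmp <- compare_assessments(a, b, wl)
  expect_equal(cmp$verdict, "consistent")
  expect_equal(cmp$group_ve_delta, 0)
  expect_equal(cmp$ve$p_value, 1)
  for (r in cmp$per_criterion) expect_equal(r$p_value, 1)
})

test_that("a uniform +1 shift across a 16-member panel is detected", {
  spec <- panel_spec(counts = c(policymaker = 4, evaluator = 6,
                                clinician = 5, patient_representative = 1),
                     score_location = 2, score_dispersion = 1, seed = 13)
  a <- simulate_assessment(spec)
  shifted <- a
  keep <- !a$quant$criterion_id %in% "plausibility"
  shifted$quant$score[keep] <- pmin(a$quant$score[keep] + 1L, 5L)
  wl <- norm_weight_list(simulate_weights(spec)$weights)
  cmp <- compare_assessments(a, shifted, wl)
  expect_equal(cmp$verdict, "inconsistent")
  expect_lt(cmp$per_criterion$severity$p_value, 0.05)
})

test_that("comparison pairs only shared panellists and reports the rest", {
  spec <- panel_spec(seed = 21)
  a <- simulate_assessment(spec)
  b <- simulate_retest(spec, a)
  keep <- c("p01", "p02", "p03")
  b3 <- mcda_assessment(b$case_id,
                        b$quant[b$quant$panellist_id %in% keep, ],
                        b$qual[b$qual$panellist_id %in% keep, ],
                        final_fw)
  wl <- norm_weight_list(simulate_weights(spec)$weights)
  cmp <- compare_assessments(a, b3, wl)
  expect_equal(cmp$n_shared, 3)
  expect_setequal(cmp$dropped_panellists, setdiff(sprintf("p%02d", 1:18), keep))
})

test_that("comparison refuses disjoint panels and mismatched frameworks", {
  spec <- panel_spec(seed = 2)
  a <- simulate_assessment(spec)
  other <- a$quant
  other$panellist_id <- sub("^p", "q", other$panellist_id)
  b <- mcda_assessment(a$case_id, other, NULL, final_fw)
  wl <- norm_weight_list(simulate_weights(spec)$weights)
  expect_error(compare_assessments(a, b, wl), "disjoint")

  pil_spec <- panel_spec(
    weight_location = 4, weight_dispersion = 0.5,
    score_location = 3, score_dispersion = 1,
    contextual_probs = c(favourable = 1, neutral = 0, unfavourable = 0),
    seed = 2)
  c_pilot <- simulate_assessment(pil_spec, pilot_fw, case_id = a$case_id)
  expect_error(compare_assessments(a, c_pilot, wl), "framework version")
})
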