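test_that("standardized scores map a scale onto the unit interval", {
  sc <- scoring_scale(0, 5)
  expect_equal(standardize_score(5, sc), 1)
  expect_equal(standardize_score(0, sc), 0)
  expect_equal(standardize_score(3, sc), 0.6)
  expect_error(standardize_score(6, sc), "outside")
  di <- scoring_scale(0, 5, dichotomous = TRUE)
  expect_equal(standardize_score(5, di), 1)
  expect_equal(standardize_score(0, di), 0)
  expect_error(standardize_score(3, di), "dichotomous")
})

test_that("value estimate is the weighted sum of standardized scores", {
  ids <- core_ids(final_fw)
  w <- equal_weights()
  ve <- value_estimate(w, stats::setNames(c(5, 5, 4, 4, 3, 3, 2, 5), ids),
                       final_fw)
  expect_equal(ve$ve, 0.775)  # (1 + 1 + .8 + .8 + .6 + .6 + .4 + 1) / 8
  expect_equal(unname(ve$vc),
               c(1, 1, 0.8, 0.8, 0.6, 0.6, 0.4, 1) / 8)

  # ceiling and floor, under arbitrary valid weights
  set.seed(5)
  for (i in 1:10) {
    rw <- stats::setNames(sample(1:5, 8, replace = TRUE), ids)
    nw <- normalize_rating_scale(rw)$weights
    expect_equal(value_estimate(nw, stats::setNames(rep(5L, 8), ids),
                                final_fw)$ve, 1)
    expect_equal(value_estimate(nw, stats::setNames(rep(0L, 8), ids),
                                final_fw)$ve, 0)
  }
})

test_that("value estimate matches an independent dot-product oracle", {
  ids <- core_ids(final_fw)
  admissible <- lapply(final_fw$core, function(cr) admissible_scores(cr$scale))
  set.seed(17)
  for (i in 1:50) {
    rw <- stats::setNames(sample(1:5, 8, replace = TRUE), ids)
    nw <- normalize_rating_scale(rw)$weights
    s <- stats::setNames(
      vapply(admissible, function(a) sample(a, 1), 0L), ids)
    got <- value_estimate(nw, s, final_fw)
    oracle <- sum(as.numeric(nw[ids]) * (s[ids] / 5))
    expect_equal(got$ve, oracle, tolerance = 1e-12)
    expect_gte(got$ve, 0)
    expect_lte(got$ve, 1)
  }
})

test_that("raising any single score never decreases the value estimate", {
  ids <- core_ids(final_fw)
  set.seed(23)
  for (i in 1:20) {
    nw <- normalize_rating_scale(
      stats::setNames(sample(1:5, 8, replace = TRUE), ids))$weights
    s <- stats::setNames(sample(0:5, 8, replace = TRUE), ids)
    s["plausibility"] <- sample(c(0L, 5L), 1)
    base <- value_estimate(nw, s, final_fw)$ve
    j <- sample(which(s < 5), 1)
    s2 <- s
    s2[j] <- if (ids[j] == "plausibility") 5L else s2[j] + 1L
    expect_gte(value_estimate(nw, s2, final_fw)$ve, base)
  }
})

test_that("value estimate validates weight/score coverage", {
  ids <- core_ids(final_fw)
  w <- equal_weights()
  s <- stats::setNames(rep(5L, 8), ids)
  expect_error(value_estimate(w[-1], s, final_fw), "missing criterion")
  expect_error(value_estimate(w, s[-1], final_fw), "missing criterion")
  expect_error(value_estimate(w * 2, s, final_fw), "unnormalized")
  expect_error(value_estimate(c(w[-1], bogus = 0.125), s, final_fw),
               "bogus|missing")
})

test_that("group report averages per-panellist value estimates", {
  w2 <- c(a = 0.5, b = 0.5)
  wl <- list(structure(list(panellist_id = "p1", weights = w2),
                       class = "normalized_weights"),
             structure(list(panellist_id = "p2", weights = w2),
                       class = "normalized_weights"))
  quant <- data.frame(
    panellist_id = rep(c("p1", "p2"), each = 2),
    criterion_id = rep(c("a", "b"), 2),
    score = c(3L, 3L, 4L, 4L))  # VE 0.6 and 0.8
  qual <- data.frame(panellist_id = c("p1", "p2"), criterion_id = "ctx",
                     rating = c("favourable", "favourable"))
  a <- mcda_assessment("case", quant, qual, tiny_fw)
  rep1 <- group_value_report(a, wl)
  expect_equal(rep1$per_panellist$ve, c(0.6, 0.8))
  expect_equal(rep1$group_ve, 0.7)
  # identical panellists: group VE equals the single-panellist VE
  quant$score <- 3L
  rep2 <- group_value_report(mcda_assessment("case", quant, qual, tiny_fw), wl)
  expect_equal(rep2$group_ve, 0.6)
  # consensus mode coincides with per-panellist mode under shared weights
  rep3 <- group_value_report(a, wl, mode = "consensus_weights")
  expect_equal(rep3$group_ve, rep1$group_ve)
  expect_equal(rep3$consensus_weights, w2)
})

test_that("panellists with incomplete scores are excluded with a warning", {
  wl <- list(structure(list(panellist_id = "p1", weights = c(a = .5, b = .5)),
                       class = "normalized_weights"),
             structure(list(panellist_id = "p2", weights = c(a = .5, b = .5)),
                       class = "normalized_weights"))
  quant <- data.frame(panellist_id = c("p1", "p1", "p2"),
                      criterion_id = c("a", "b", "a"), score = 5L)
  a <- mcda_assessment("case", quant, NULL, tiny_fw)
  expect_warning(rep <- group_value_report(a, wl), "incomplete")
  expect_equal(rep$excluded, "p2")
  expect_equal(rep$n_panel, 1)
  expect_equal(rep$group_ve, 1)
})

test_that("scoring errors on a panellist without weights and on empty input", {
  wl <- list(structure(list(panellist_id = "p1", weights = c(a = .5, b = .5)),
                       class = "normalized_weights"))
  quant <- data.frame(panellist_id = rep("p9", 2),
                      criterion_id = c("a", "b"), score = 5L)
  a <- mcda_assessment("case", quant, NULL, tiny_fw)
  expect_error(group_value_report(a, wl), "p9")
  expect_error(mcda_assessment("case", quant[0, ], NULL, tiny_fw) |>
                 group_value_report(wl), "empty|no quantitative")
})

test_that("contextual tallies sum to one and report the dominant direction", {
  ctx <- contextual_ids(final_fw)
  mk <- function(n_f, n_n, n_u, id = "management_impact") {
    data.frame(panellist_id = sprintf("p%02d", seq_len(n_f + n_n + n_u)),
               criterion_id = id,
               rating = rep(c("favourable", "neutral", "unfavourable"),
                            c(n_f, n_n, n_u)))
  }
  t1 <- tally_contextual(mk(0, 0, 16), "management_impact")
  expect_equal(t1$pct_unfavourable, 100)
  expect_equal(t1$dominant, "unfavourable")

  t2 <- tally_contextual(mk(12, 1, 0), "management_impact")
  expect_equal(t2$pct_favourable, 92)  # 12/13 = 92.3%
  expect_equal(t2$dominant, "favourable")
  expect_equal(t2$frac_favourable + t2$frac_neutral + t2$frac_unfavourable, 1)

  t3 <- tally_contextual(mk(6, 0, 6), "management_impact")
  expect_equal(t3$dominant, "mixed")

  expect_error(tally_contextual(mk(1, 0, 0, id = "severity"), ctx),
               "non-contextual")
  expect_error(tally_contextual(mk(1, 0, 0), c("management_impact", "costs_budget_impact")),
               "no ratings")
})
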