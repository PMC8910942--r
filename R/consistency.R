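# Test/re-test consistency checking.
#
# The re-test repeats the appraisal of a case after an interval; paired
# differences in scores (per criterion) and in per-panellist value estimates
# are tested with a Wilcoxon signed-rank test, exact by default.

#' Wilcoxon signed-rank test (exact by enumeration, from scratch)
#'
#' Tests the symmetry about zero of the paired differences `d = x - y`.
#' Zero differences are discarded (classic treatment; Pratt's zero-rank
#' method available), absolute differences are ranked with midranks for
#' ties, and `W+` / `W-` are the rank sums of positive and negative
#' differences. For `n_nonzero <= exact_limit` the two-sided p-value is
#' exact: the null distribution over all `2^n` equiprobable sign assignments
#' of the observed (mid)ranks is computed in full, and
#' `p = min(1, 2 * min(P(W+ <= w), P(W+ >= w)))`. Beyond the limit a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_limit maximum `n_nonzero` for the exact path (default 20;
#'   the exact null distribution over the observed ranks is always cheap to
#'   compute, the cap mirrors the point where the normal approximation is
#'   adequate).
#' @param zero_method `"discard"` drops zero differences before ranking;
#'   `"pratt"` ranks them with the rest but drops their ranks from both sums.
#' @return an object of class `mcda_wilcoxon`: `n`, `n_nonzero`, `w_plus`,
#'   `w_minus`, `statistic` (`min(w_plus, w_minus)`), `p_value` (two-sided),
#'   `method`, `ties`, `no_information` (all differences zero).
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))$p_value  # 0.0625
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 20,
                                 zero_method = c("discard", "pratt")) {
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y))
    stop_mcda("length mismatch: ", length(x), " vs ", length(y))
  if (!length(x)) stop_mcda("empty input")
  d <- as.numeric(x) - as.numeric(y)
  if (anyNA(d)) stop_mcda("missing values in paired differences")
  nz <- d != 0
  n_nonzero <- sum(nz)
  if (n_nonzero == 0) {
    return(structure(
      list(n = length(d), n_nonzero = 0L, w_plus = 0, w_minus = 0,
           statistic = 0, p_value = 1, method = "exact", ties = FALSE,
           no_information = TRUE),
      class = "mcda_wilcoxon"))
  }
  if (zero_method == "pratt") {
    r_all <- rank(abs(d))
    r <- r_all[nz]
  } else {
    r <- rank(abs(d[nz]))
  }
  dn <- d[nz]
  w_plus <- sum(r[dn > 0])
  w_minus <- sum(r[dn < 0])
  ties <- anyDuplicated(r) > 0
  if (n_nonzero <= exact_limit) {
    p <- exact_signed_rank_p(r, w_plus)
    method <- "exact"
  } else {
    p <- approx_signed_rank_p(r, w_plus)
    method <- "normal_approximation"
  }
  structure(
    list(n = length(d), n_nonzero = as.integer(n_nonzero),
         w_plus = w_plus, w_minus = w_minus,
         statistic = min(w_plus, w_minus), p_value = p, method = method,
         ties = ties, no_information = FALSE),
    class = "mcda_wilcoxon"
  )
}

# Exact null distribution of W+ over all 2^n sign assignments of the observed
# (mid)ranks, by generating-function convolution. Midranks are doubled so all
# rank sums are integers; prob[k] is then P(2 W+ = k - 1).
exact_signed_rank_p <- function(ranks, w_plus) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  prob <- numeric(total + 1L)
  prob[1L] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), prob[seq_len(total + 1L - rk)])
    prob <- (prob + shifted) / 2
  }
  w2 <- as.integer(round(2 * w_plus))
  p_lo <- sum(prob[seq_len(w2 + 1L)])
  p_hi <- sum(prob[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_lo, p_hi))
}

# Normal approximation: W+ is a sum of r_i * B_i with B_i iid Bernoulli(1/2),
# so mean = sum(r)/2 and variance = sum(r^2)/4 (midranks make this the
# tie-corrected variance). Continuity correction of 1/2 toward the mean.
approx_signed_rank_p <- function(ranks, w_plus) {
  mu <- sum(ranks) / 2
  sigma <- sqrt(sum(ranks^2) / 4)
  if (sigma == 0) return(1)
  dev <- max(abs(w_plus - mu) - 0.5, 0)
  min(1, 2 * stats::pnorm(-dev / sigma))
}

#' @export
print.mcda_wilcoxon <- function(x, ...) {
  if (x$no_information) {
    cat("<wilcoxon signed-rank> all differences zero (no information); p = 1\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<wilcoxon signed-rank> n = %d (nonzero %d), W+ = %g, W- = %g, statistic = %g\n",
    x$n, x$n_nonzero, x$w_plus, x$w_minus, x$statistic))
  cat(sprintf("  two-sided p = %.4g (%s%s)\n", x$p_value, x$method,
              if (x$ties) ", midranks for ties" else ""))
  invisible(x)
}

# ---- assessment comparison -------------------------------------------------

#' Compare a test and a re-test assessment of the same case
#'
#' Pairs the two assessments on their shared panellists and runs the Wilcoxon
#' signed-rank test on every core criterion's score pairs and on the paired
#' per-panellist value estimates. The verdict is `"consistent"` when no
#' compared quantity reaches significance at `alpha`, and `"inconsistent"`
#' otherwise. Panellists present in only one assessment are dropped and
#' listed in the pairing report.
#'
#' @param test,retest two [mcda_assessment()] objects with the same case id
#'   and framework version.
#' @param panel_weights list of `normalized_weights` covering the shared
#'   panellists (used for the value-estimate comparison).
#' @param framework an [mcda_framework()]; defaults to the test assessment's.
#' @param alpha significance level in (0, 1).
#' @param exact_limit,zero_method passed to [wilcoxon_signed_rank()].
#' @return an object of class `retest_comparison`: per-criterion results,
#'   the VE-level result, `group_ve_delta` (re-test minus test), `verdict`,
#'   and the pairing report.
#' @export
compare_assessments <- function(test, retest, panel_weights,
                                framework = test$framework, alpha = 0.05,
                                exact_limit = 20,
                                zero_method = c("discard", "pratt")) {
  zero_method <- match.arg(zero_method)
  stopifnot(inherits(test, "mcda_assessment"),
            inherits(retest, "mcda_assessment"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_mcda("alpha must be in (0, 1)")
  if (!identical(test$framework_version, retest$framework_version))
    stop_mcda("mismatched framework versions: '", test$framework_version,
              "' vs '", retest$framework_version, "'")
  if (!identical(test$case_id, retest$case_id))
    stop_mcda("assessments are for different cases: '", test$case_id,
              "' vs '", retest$case_id, "'")
  p_test <- unique(test$quant$panellist_id)
  p_retest <- unique(retest$quant$panellist_id)
  shared <- intersect(p_test, p_retest)
  if (!length(shared)) stop_mcda("disjoint panels: no shared panellists")
  dropped <- setdiff(union(p_test, p_retest), shared)

  ids <- core_ids(framework)
  score_of <- function(a, p, id) {
    v <- a$quant$score[a$quant$panellist_id == p & a$quant$criterion_id == id]
    if (length(v) == 1L) v else NA_real_
  }
  per_criterion <- list()
  for (id in ids) {
    xs <- vapply(shared, score_of, 0, a = test, id = id)
    ys <- vapply(shared, score_of, 0, a = retest, id = id)
    ok <- !is.na(xs) & !is.na(ys)
    per_criterion[[id]] <- if (any(ok))
      wilcoxon_signed_rank(xs[ok], ys[ok], exact_limit, zero_method)
    else NULL
  }

  wl <- as_weight_list(panel_weights)
  ve_pair <- function(a, p) {
    v <- a$quant[a$quant$panellist_id == p, ]
    vec <- stats::setNames(v$score, v$criterion_id)
    if (!all(ids %in% names(vec)) || is.null(wl[[p]])) return(NA_real_)
    value_estimate(wl[[p]], vec[ids], framework)$ve
  }
  ve_test <- vapply(shared, ve_pair, 0, a = test)
  ve_retest <- vapply(shared, ve_pair, 0, a = retest)
  ok <- !is.na(ve_test) & !is.na(ve_retest)
  if (!any(ok)) stop_mcda("no shared panellist has complete scores and weights")
  ve_result <- wilcoxon_signed_rank(ve_test[ok], ve_retest[ok],
                                    exact_limit, zero_method)
  group_ve_delta <- mean(ve_retest[ok]) - mean(ve_test[ok])

  ps <- c(vapply(Filter(Negate(is.null), per_criterion), `[[`, 0, "p_value"),
          ve_result$p_value)
  verdict <- if (any(ps < alpha)) "inconsistent" else "consistent"

  structure(
    list(case_id = test$case_id, alpha = alpha,
         per_criterion = per_criterion, ve = ve_result,
         group_ve_test = mean(ve_test[ok]),
         group_ve_retest = mean(ve_retest[ok]),
         group_ve_delta = group_ve_delta,
         verdict = verdict,
         n_shared = length(shared), dropped_panellists = dropped),
    class = "retest_comparison"
  )
}

#' @export
print.retest_comparison <- function(x, ...) {
  cat(sprintf("<retest_comparison '%s'> %d shared panellists, alpha = %g\n",
              x$case_id, x$n_shared, x$alpha))
  cat("Per-criterion Wilcoxon signed-rank p-values:\n")
  for (id in names(x$per_criterion)) {
    r <- x$per_criterion[[id]]
    if (is.null(r)) next
    flag <- if (r$p_value < x$alpha) " *" else ""
    cat(sprintf("  %-22s p = %.4g (%s)%s\n", id, r$p_value, r$method, flag))
  }
  cat(sprintf("Value estimates: p = %.4g; group VE %.2f -> %.2f (delta %+.3f)\n",
              x$ve$p_value, x$group_ve_test, x$group_ve_retest,
              x$group_ve_delta))
  if (length(x$dropped_panellists))
    cat("Unpaired panellists:", paste(x$dropped_panellists, collapse = ", "),
        "\n")
  cat("Verdict:", x$verdict, "\n")
  invisible(x)
}
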