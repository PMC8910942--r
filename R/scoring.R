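# The linear additive value model.
#
# Each quantitative criterion contributes VC_x = W_x * S_x, the product of
# the panellist's normalized weight and the standardized score; the value
# estimate VE = sum_x VC_x is a convex combination of standardized scores and
# therefore lies in [0, 1], reaching 1 exactly when every score sits at its
# scale maximum.

QUAL_LEVELS <- c("favourable", "neutral", "unfavourable")

#' Construct a case assessment
#'
#' One case study's panel ratings: a quantitative score table over the core
#' criteria and a qualitative rating table over the contextual criteria.
#'
#' @param case_id identifier of the case (e.g. the requested medicine).
#' @param quant data.frame with columns `panellist_id`, `criterion_id`,
#'   `score` (integers on each criterion's scale).
#' @param qual data.frame with columns `panellist_id`, `criterion_id`,
#'   `rating` (favourable / neutral / unfavourable); may have zero rows.
#' @param framework the [mcda_framework()] the assessment was scored under.
#' @param description free text.
#' @return an object of class `mcda_assessment`.
#' @export
mcda_assessment <- function(case_id, quant, qual = NULL, framework,
                            description = "") {
  stopifnot(inherits(framework, "mcda_framework"))
  if (!is.data.frame(quant) ||
      !all(c("panellist_id", "criterion_id", "score") %in% names(quant)))
    stop_mcda("quant must have columns panellist_id, criterion_id, score")
  if (is.null(qual))
    qual <- data.frame(panellist_id = character(), criterion_id = character(),
                       rating = character())
  if (!all(c("panellist_id", "criterion_id", "rating") %in% names(qual)))
    stop_mcda("qual must have columns panellist_id, criterion_id, rating")
  scales <- core_scales(framework)
  bad <- setdiff(unique(quant$criterion_id), names(scales))
  if (length(bad))
    stop_mcda("quantitative score on non-core criterion '", bad[1], "'")
  for (i in seq_len(nrow(quant)))
    check_score(quant$score[i], scales[[quant$criterion_id[i]]],
                what = paste0("score for ", quant$panellist_id[i], "/",
                              quant$criterion_id[i]))
  badq <- setdiff(unique(qual$criterion_id), contextual_ids(framework))
  if (length(badq))
    stop_mcda("qualitative rating on non-contextual criterion '", badq[1], "'")
  badr <- setdiff(unique(qual$rating), QUAL_LEVELS)
  if (length(badr))
    stop_mcda("unknown rating '", badr[1], "'; use ",
              paste(QUAL_LEVELS, collapse = "/"))
  structure(
    list(case_id = as.character(case_id), description = description,
         quant = quant[c("panellist_id", "criterion_id", "score")],
         qual = qual[c("panellist_id", "criterion_id", "rating")],
         framework_version = framework$version_tag, framework = framework),
    class = "mcda_assessment"
  )
}

#' @export
print.mcda_assessment <- function(x, ...) {
  cat(sprintf("<mcda_assessment '%s'> framework '%s'\n", x$case_id,
              x$framework_version))
  cat(sprintf("  %d quantitative scores from %d panellists; %d contextual ratings\n",
              nrow(x$quant), length(unique(x$quant$panellist_id)),
              nrow(x$qual)))
  invisible(x)
}

#' Value estimate of one panellist's scores
#'
#' Computes the per-criterion value contributions `VC_x = W_x * S_x` and the
#' value estimate `VE = sum_x VC_x` for a single panellist. Weights must be
#' normalized (sum to 1) and weights and scores must cover exactly the core
#' criteria of the framework.
#'
#' @param weights a `normalized_weights` object or a named vector summing
#'   to 1 over the core criterion ids.
#' @param scores named integer vector of raw scores, one per core criterion.
#' @param framework an [mcda_framework()].
#' @return list with `ve` (the value estimate, in \[0, 1\]), `vc` (named
#'   value contributions), `s` (standardized scores) and `w` (weights used).
#' @examples
#' fw <- default_framework("final")
#' w <- stats::setNames(rep(1 / 8, 8), core_ids(fw))
#' s <- stats::setNames(c(5, 5, 4, 4, 3, 3, 2, 5), core_ids(fw))
#' value_estimate(w, s, fw)$ve  # 0.775
#' @export
value_estimate <- function(weights, scores, framework) {
  stopifnot(inherits(framework, "mcda_framework"))
  if (inherits(weights, "normalized_weights")) weights <- weights$weights
  ids <- core_ids(framework)
  miss_w <- setdiff(ids, names(weights))
  if (length(miss_w)) stop_mcda("weights missing criterion '", miss_w[1], "'")
  extra_w <- setdiff(names(weights), ids)
  if (length(extra_w))
    stop_mcda("weight for non-core criterion '", extra_w[1], "'")
  miss_s <- setdiff(ids, names(scores))
  if (length(miss_s)) stop_mcda("scores missing criterion '", miss_s[1], "'")
  extra_s <- setdiff(names(scores), ids)
  if (length(extra_s))
    stop_mcda("score for non-core criterion '", extra_s[1], "'")
  w <- as.numeric(weights[ids])
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-8)
    stop_mcda("unnormalized weights: values must be positive and sum to 1")
  scales <- core_scales(framework)
  s <- vapply(ids, function(id) standardize_score(scores[[id]], scales[[id]]),
              numeric(1))
  vc <- stats::setNames(w * s, ids)
  list(ve = sum(vc), vc = vc, s = stats::setNames(s, ids),
       w = stats::setNames(w, ids))
}

#' Tally contextual-tool ratings
#'
#' Percentage breakdown of favourable / neutral / unfavourable ratings per
#' contextual criterion, with the dominant direction (the strict-majority
#' category, or `"mixed"` when none holds more than half the ratings).
#' Display percentages are integers (rounded half to even); exact fractions
#' are retained.
#'
#' @param ratings data.frame with columns `panellist_id`, `criterion_id`,
#'   `rating`.
#' @param contextual_criteria character vector of contextual criterion ids
#'   (or a list of qualitative [criterion()] objects).
#' @return data.frame with one row per contextual criterion: counts, exact
#'   fractions, display percentages and `dominant`.
#' @export
tally_contextual <- function(ratings, contextual_criteria) {
  if (is.list(contextual_criteria) && !is.character(contextual_criteria))
    contextual_criteria <- vapply(contextual_criteria, `[[`, "", "id")
  bad <- setdiff(unique(ratings$criterion_id), contextual_criteria)
  if (length(bad))
    stop_mcda("rating on non-contextual criterion '", bad[1], "'")
  badr <- setdiff(unique(ratings$rating), QUAL_LEVELS)
  if (length(badr)) stop_mcda("unknown rating '", badr[1], "'")
  rows <- lapply(contextual_criteria, function(id) {
    r <- ratings$rating[ratings$criterion_id == id]
    if (!length(r))
      stop_mcda("no ratings for contextual criterion '", id, "'")
    counts <- table(factor(r, QUAL_LEVELS))
    frac <- as.numeric(counts) / length(r)
    dominant <- if (any(frac > 0.5)) QUAL_LEVELS[which.max(frac)] else "mixed"
    data.frame(criterion_id = id, n = length(r),
               n_favourable = as.integer(counts[1]),
               n_neutral = as.integer(counts[2]),
               n_unfavourable = as.integer(counts[3]),
               frac_favourable = frac[1], frac_neutral = frac[2],
               frac_unfavourable = frac[3],
               pct_favourable = display_pct(frac[1]),
               pct_neutral = display_pct(frac[2]),
               pct_unfavourable = display_pct(frac[3]),
               dominant = dominant)
  })
  do.call(rbind, rows)
}

# ---- group value report ----------------------------------------------------

as_weight_list <- function(panel_weights) {
  if (inherits(panel_weights, "normalized_weights"))
    panel_weights <- list(panel_weights)
  if (!is.list(panel_weights) ||
      !all(vapply(panel_weights, inherits, TRUE, "normalized_weights")))
    stop_mcda("panel_weights must be a list of normalized_weights")
  ids <- vapply(panel_weights, `[[`, "", "panellist_id")
  if (anyDuplicated(ids)) stop_mcda("duplicate panellist in panel_weights")
  stats::setNames(panel_weights, ids)
}

#' Group value report for a case assessment
#'
#' Computes the full panel-level appraisal of one case: per-panellist value
#' estimates, the group value estimate (arithmetic mean across panellists),
#' per-criterion mean value contributions, and contextual-tool tallies.
#'
#' In `per_panellist` mode (the default), each panellist's own normalized
#' weights multiply their own standardized scores. In `consensus_weights`
#' mode a single consensus vector — the mean of the panel's normalized
#' weights — is used for everyone; by linearity of the additive model both
#' modes coincide when all panellists share one weight vector.
#'
#' Panellists with an incomplete quantitative score vector are excluded from
#' the value estimate with a warning (no imputation is attempted); their ids
#' are listed in the report.
#'
#' @param assessment an [mcda_assessment()].
#' @param panel_weights list of `normalized_weights`, one per scoring
#'   panellist (in `per_panellist` mode).
#' @param framework an [mcda_framework()]; defaults to the assessment's own.
#' @param mode `"per_panellist"` or `"consensus_weights"`.
#' @return an object of class `value_report`.
#' @export
group_value_report <- function(assessment, panel_weights,
                               framework = assessment$framework,
                               mode = c("per_panellist", "consensus_weights")) {
  mode <- match.arg(mode)
  stopifnot(inherits(assessment, "mcda_assessment"),
            inherits(framework, "mcda_framework"))
  wl <- as_weight_list(panel_weights)
  ids <- core_ids(framework)
  sc <- assessment$quant
  if (!nrow(sc)) stop_mcda("empty assessment: no quantitative scores")
  panellists <- unique(sc$panellist_id)

  complete <- character()
  score_vecs <- list()
  for (p in panellists) {
    v <- sc[sc$panellist_id == p, ]
    vec <- stats::setNames(v$score, v$criterion_id)
    if (all(ids %in% names(vec))) {
      complete <- c(complete, p)
      score_vecs[[p]] <- vec[ids]
    }
  }
  excluded <- setdiff(panellists, complete)
  if (length(excluded))
    warning("excluded panellist(s) with incomplete scores: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  if (!length(complete)) stop_mcda("no assessable panellists")
  no_weights <- setdiff(complete, names(wl))
  if (length(no_weights))
    stop_mcda("panellist '", no_weights[1], "' has scores but no weights")

  if (mode == "consensus_weights") {
    wmat <- vapply(wl[complete], function(nw) nw$weights[ids], numeric(length(ids)))
    consensus <- stats::setNames(rowMeans(wmat), ids)
    weights_for <- function(p) consensus
  } else {
    consensus <- NULL
    weights_for <- function(p) wl[[p]]$weights
  }

  per <- lapply(complete, function(p)
    value_estimate(weights_for(p), score_vecs[[p]], framework))
  ves <- vapply(per, `[[`, 0, "ve")
  vc_mat <- vapply(per, `[[`, numeric(length(ids)), "vc")
  vc_mean <- stats::setNames(rowMeans(vc_mat), ids)

  contextual <- if (nrow(assessment$qual))
    tally_contextual(assessment$qual, contextual_ids(framework))
  else NULL

  structure(
    list(case_id = assessment$case_id, mode = mode,
         framework_version = framework$version_tag,
         per_panellist = data.frame(panellist_id = complete, ve = ves),
         group_ve = mean(ves), vc_mean = vc_mean,
         contextual = contextual, consensus_weights = consensus,
         excluded = excluded, n_panel = length(complete)),
    class = "value_report"
  )
}

#' @export
print.value_report <- function(x, ...) {
  cat(sprintf("<value_report '%s'> framework '%s', %d panellists (%s)\n",
              x$case_id, x$framework_version, x$n_panel, x$mode))
  cat(sprintf("Group value estimate: %.2f (maximum value of 1)\n", x$group_ve))
  cat("Mean value contribution per criterion:\n")
  vc <- sort(x$vc_mean, decreasing = TRUE)
  for (i in seq_along(vc))
    cat(sprintf("  %-22s %.3f\n", names(vc)[i], vc[i]))
  if (!is.null(x$contextual)) {
    cat("Contextual tool (% favourable / neutral / unfavourable):\n")
    for (i in seq_len(nrow(x$contextual))) {
      r <- x$contextual[i, ]
      cat(sprintf("  %-24s %3d%% / %3d%% / %3d%%  -> %s\n", r$criterion_id,
                  r$pct_favourable, r$pct_neutral, r$pct_unfavourable,
                  r$dominant))
    }
  }
  if (length(x$excluded))
    cat("Excluded (incomplete scores):", paste(x$excluded, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.value_report <- function(object, ...) {
  cat(sprintf("Case '%s': group VE %.2f over %d panellists; per-panellist VE range %.2f-%.2f\n",
              object$case_id, object$group_ve, object$n_panel,
              min(object$per_panellist$ve), max(object$per_panellist$ve)))
  invisible(object)
}
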