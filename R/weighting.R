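# Weight elicitation and aggregation.
#
# Each panellist rates the relative importance of every core criterion on a
# non-hierarchical 5-point scale (1 = lowest relative importance, 5 =
# highest). Weights are then normalized to sum to 1 per panellist before
# entering the additive value model.

#' A panellist's raw importance weights
#'
#' @param panellist_id identifier of the panellist.
#' @param weights named numeric vector, one integer in 1..5 per core
#'   criterion id.
#' @return an object of class `raw_weights`.
#' @export
raw_weights <- function(panellist_id, weights) {
  check_raw_weight_values(weights)
  structure(list(panellist_id = as.character(panellist_id),
                 weights = weights),
            class = "raw_weights")
}

check_raw_weight_values <- function(weights) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop_mcda("weights must be a named vector of criterion ids")
  bad <- which(!(weights %in% 1:5))
  if (length(bad))
    stop_mcda("weight for '", names(weights)[bad[1]], "' is ",
              weights[bad[1]], "; must be an integer in 1..5")
  invisible(weights)
}

#' Normalize raw weights by the rating-scale method
#'
#' Divides each raw weight by the sum of the panellist's weights across all
#' criteria, so the normalized weights are positive and sum to 1:
#' `W_x = w_x / sum_j w_j`.
#'
#' @param raw a [raw_weights()] object, or a named numeric vector of raw
#'   weights.
#' @param check_range validate that raw values are integers in 1..5 (the
#'   elicitation scale). Disable only for generic positive vectors.
#' @return an object of class `normalized_weights`: a list with
#'   `panellist_id` and `weights` (named fractions summing to 1).
#' @examples
#' w <- normalize_rating_scale(raw_weights("p1", c(
#'   severity = 5, urgency = 5, efficacy = 4, safety = 4,
#'   internal_validity = 4, therapeutic_benefit = 4,
#'   external_validity = 3, plausibility = 3)))
#' sum(w$weights)  # 1
#' @export
normalize_rating_scale <- function(raw, check_range = TRUE) {
  if (inherits(raw, "raw_weights")) {
    id <- raw$panellist_id
    w <- raw$weights
  } else {
    id <- NA_character_
    w <- raw
  }
  if (!length(w)) stop_mcda("no weights supplied")
  if (anyNA(w)) stop_mcda("missing weight for '", names(w)[which(is.na(w))[1]], "'")
  if (check_range) check_raw_weight_values(w)
  if (any(w <= 0)) stop_mcda("weights must be positive")
  structure(list(panellist_id = id, weights = w / sum(w)),
            class = "normalized_weights")
}

#' Normalize weights by the point-allocation method
#'
#' For hierarchically elicited preferences, each criterion rating is
#' multiplied by the weight of the domain it belongs to, and the products are
#' rescaled onto \[0, 1\] by dividing by their sum — so the result is again a
#' normalized weight vector summing to 1, on the same contract as
#' [normalize_rating_scale()].
#'
#' @param ratings named positive numeric vector, criterion id -> points.
#' @param domain_weights named numeric vector, domain -> fraction.
#' @param domain_of named character vector, criterion id -> domain.
#' @param panellist_id optional identifier carried through.
#' @return a `normalized_weights` object.
#' @examples
#' normalize_point_allocation(
#'   ratings = c(a = 1, b = 1, c = 1, d = 1),
#'   domain_weights = c(clinical = 0.6, economic = 0.4),
#'   domain_of = c(a = "clinical", b = "clinical",
#'                 c = "economic", d = "economic"))$weights
#' # a, b -> 0.3; c, d -> 0.2
#' @export
normalize_point_allocation <- function(ratings, domain_weights, domain_of,
                                       panellist_id = NA_character_) {
  if (!length(ratings) || is.null(names(ratings)))
    stop_mcda("ratings must be a named vector of criterion ids")
  if (any(ratings <= 0) || anyNA(ratings))
    stop_mcda("non-positive rating for '",
              names(ratings)[which(!(ratings > 0))[1]], "'")
  dom <- domain_of[names(ratings)]
  if (anyNA(dom))
    stop_mcda("criterion '", names(ratings)[which(is.na(dom))[1]],
              "' has no domain in domain_of")
  dw <- domain_weights[dom]
  if (anyNA(dw))
    stop_mcda("domain '", dom[which(is.na(dw))[1]],
              "' missing from domain_weights")
  u <- ratings * as.numeric(dw)
  structure(list(panellist_id = as.character(panellist_id),
                 weights = u / sum(u)),
            class = "normalized_weights")
}

#' @export
print.normalized_weights <- function(x, ...) {
  cat(sprintf("<normalized_weights> panellist %s\n", x$panellist_id))
  print(round(x$weights, 4))
  invisible(x)
}

# ---- panel aggregation -----------------------------------------------------

check_roster <- function(roster) {
  if (!is.data.frame(roster) ||
      !all(c("panellist_id", "profile") %in% names(roster)))
    stop_mcda("roster must be a data.frame with panellist_id and profile")
  bad <- setdiff(unique(roster$profile), panel_profiles())
  if (length(bad)) stop_mcda("unknown profile: ", bad[1])
  if (anyDuplicated(roster$panellist_id))
    stop_mcda("duplicate panellist_id in roster")
  invisible(roster)
}

weights_long <- function(panel) {
  if (is.data.frame(panel)) {
    need <- c("panellist_id", "criterion_id", "weight")
    if (!all(need %in% names(panel)))
      stop_mcda("weights table needs columns ", paste(need, collapse = ", "))
    return(panel[c("panellist_id", "criterion_id", "weight")])
  }
  if (is.list(panel) && all(vapply(panel, inherits, TRUE, "raw_weights"))) {
    return(do.call(rbind, lapply(panel, function(rw)
      data.frame(panellist_id = rw$panellist_id,
                 criterion_id = names(rw$weights),
                 weight = as.numeric(rw$weights)))))
  }
  stop_mcda("panel must be a long weights data.frame or a list of raw_weights")
}

summarize_stratum <- function(w, criteria_order) {
  agg <- lapply(split(w$weight, factor(w$criterion_id, criteria_order)),
                function(v) c(mean = mean(v),
                              sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                              n = length(v)))
  out <- data.frame(criterion_id = criteria_order,
                    mean = vapply(agg, `[[`, 0, "mean"),
                    sd = vapply(agg, `[[`, 0, "sd"),
                    n = as.integer(vapply(agg, `[[`, 0, "n")),
                    row.names = NULL)
  out <- out[order(-out$mean, out$criterion_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate panel weights
#'
#' Per-criterion mean and dispersion of the raw 1..5 importance weights,
#' overall and stratified by professional profile, reported in descending
#' mean order (the "mean +/- SD" relative-importance summary). Dispersion is
#' the sample standard deviation (n - 1 denominator) by default, the usual
#' reporting convention for small expert panels; a stratum of one panellist
#' reports its SD as not available.
#'
#' @param panel long data.frame with columns `panellist_id`, `criterion_id`,
#'   `weight`, or a list of [raw_weights()].
#' @param roster data.frame with columns `panellist_id`, `profile`.
#' @param dispersion `"sample"` (n - 1) or `"population"` (n).
#' @return an object of class `weight_summary`: list with `overall` and
#'   `by_profile` data.frames (criterion_id, mean, sd, n) and `panel_size`.
#' @export
aggregate_weights <- function(panel, roster,
                              dispersion = c("sample", "population")) {
  dispersion <- match.arg(dispersion)
  check_roster(roster)
  w <- weights_long(panel)
  if (!nrow(w)) stop_mcda("empty panel: no weights supplied")
  unknown <- setdiff(unique(w$panellist_id), roster$panellist_id)
  if (length(unknown))
    stop_mcda("weights for unknown panellist '", unknown[1], "'")
  check_raw_weight_values(stats::setNames(w$weight, w$criterion_id))
  crits <- unique(w$criterion_id)
  overall <- summarize_stratum(w, crits)
  w$profile <- roster$profile[match(w$panellist_id, roster$panellist_id)]
  by_profile <- lapply(split(w, w$profile), summarize_stratum, crits)
  if (dispersion == "population") {
    popsd <- function(df, raw) {
      for (i in seq_len(nrow(df))) {
        v <- raw$weight[raw$criterion_id == df$criterion_id[i]]
        df$sd[i] <- sqrt(mean((v - mean(v))^2))
      }
      df
    }
    overall <- popsd(overall, w)
    by_profile <- lapply(names(by_profile), function(p)
      popsd(by_profile[[p]], w[w$profile == p, ]))
    names(by_profile) <- sort(unique(w$profile))
  }
  structure(list(overall = overall, by_profile = by_profile,
                 panel_size = length(unique(w$panellist_id)),
                 dispersion = dispersion),
            class = "weight_summary")
}

#' @export
print.weight_summary <- function(x, ...) {
  cat(sprintf("<weight_summary> %d panellists, %s SD\n", x$panel_size,
              x$dispersion))
  cat("Relative importance (mean +/- SD), descending:\n")
  for (i in seq_len(nrow(x$overall))) {
    r <- x$overall[i, ]
    sd_txt <- if (is.na(r$sd)) "NA" else sprintf("%.1f", r$sd)
    cat(sprintf("  %-22s %.1f +/- %s  (n = %d)\n",
                r$criterion_id, r$mean, sd_txt, r$n))
  }
  invisible(x)
}

#' Panel composition by professional profile
#'
#' Counts and percentage shares of the four profiles on the roster. Display
#' percentages are rounded to integers (half to even); the exact fractions
#' are retained.
#'
#' @param roster data.frame with columns `panellist_id`, `profile`.
#' @return data.frame with `profile`, `n`, `fraction`, `percent`.
#' @examples
#' roster <- data.frame(
#'   panellist_id = sprintf("p%02d", 1:18),
#'   profile = rep(c("evaluator", "clinician", "policymaker",
#'                   "patient_representative"), c(7, 5, 5, 1)))
#' panel_composition(roster)  # evaluators: 39%
#' @export
panel_composition <- function(roster) {
  check_roster(roster)
  n <- table(factor(roster$profile, panel_profiles()))
  frac <- as.numeric(n) / nrow(roster)
  data.frame(profile = names(n), n = as.integer(n), fraction = frac,
             percent = display_pct(frac), row.names = NULL)
}
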