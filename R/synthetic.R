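# Seeded synthetic panels.
#
# Weights and quantitative scores are drawn from a discretized truncated
# normal on the criterion's scale: a latent normal draw is rounded to the
# nearest integer and clamped to the scale. The latent location is
# mean-calibrated by root-finding so the discrete distribution's expectation
# equals the requested location (plain discretization would bias locations
# near the scale ends toward the centre). Dichotomous criteria are drawn
# Bernoulli between their endpoints with the success probability implied by
# the location. One global seed feeds independent per-purpose substreams, so
# weights, assessments and re-tests draw from separate streams.

# pmf of round-and-clamp of N(mu, sd) on integers lo..hi
discnorm_pmf <- function(mu, sd, lo, hi) {
  k <- lo:hi
  if (sd == 0) {
    hit <- pmin(pmax(round(mu), lo), hi)
    return(as.numeric(k == hit))
  }
  upper <- stats::pnorm(k + 0.5, mu, sd)
  lower <- stats::pnorm(k - 0.5, mu, sd)
  p <- upper - lower
  p[1] <- upper[1]
  p[length(k)] <- 1 - lower[length(k)]
  p
}

discnorm_mean <- function(mu, sd, lo, hi) sum((lo:hi) * discnorm_pmf(mu, sd, lo, hi))

# latent mu such that the discretized distribution has mean `target`
calibrate_mu <- function(target, sd, lo, hi) {
  if (sd == 0) return(target)
  if (target <= lo) return(lo - 6 * sd - 1)
  if (target >= hi) return(hi + 6 * sd + 1)
  lower <- lo - 6 * sd - 1
  upper <- hi + 6 * sd + 1
  if (discnorm_mean(lower, sd, lo, hi) >= target) return(lower)
  if (discnorm_mean(upper, sd, lo, hi) <= target) return(upper)
  stats::uniroot(function(m) discnorm_mean(m, sd, lo, hi) - target,
                 c(lower, upper), tol = 1e-9)$root
}

draw_discnorm <- function(n, location, dispersion, lo, hi) {
  mu <- calibrate_mu(location, dispersion, lo, hi)
  sample(lo:hi, n, replace = TRUE, prob = discnorm_pmf(mu, dispersion, lo, hi))
}

resolve_param <- function(x, ids, what) {
  if (length(x) == 1L && is.null(names(x)))
    return(stats::setNames(rep(as.numeric(x), length(ids)), ids))
  miss <- setdiff(ids, names(x))
  if (length(miss))
    stop_mcda(what, " missing criterion '", miss[1], "'")
  stats::setNames(as.numeric(x[ids]), ids)
}

#' Specify a synthetic panel
#'
#' Declares the statistical structure of a simulated appraisal panel: its
#' composition, the location/dispersion of criterion importance weights on
#' the 1..5 elicitation scale (optionally per professional profile), the
#' location/dispersion of case-study scores on each criterion's scale, the
#' contextual rating probabilities, and the re-test drift model. The
#' defaults emulate an 18-member multidisciplinary committee (7 evaluators,
#' 5 clinicians, 5 policymakers, 1 patient representative) with high
#' between-panellist agreement on weights (SDs of 0.6-0.7) and weight
#' locations spanning 3.6 (plausibility) to 4.7 (urgency).
#'
#' @param counts named non-negative integers per profile (see
#'   [panel_profiles()]); total >= 1.
#' @param weight_location named vector of per-criterion weight means on the
#'   1..5 scale, or a list of such vectors keyed by profile.
#' @param weight_dispersion matching SDs (>= 0); same shapes accepted.
#' @param score_location per-criterion score mean for a simulated case, or a
#'   single value recycled over all core criteria.
#' @param score_dispersion matching SDs (>= 0).
#' @param contextual_probs probability triple `(favourable, neutral,
#'   unfavourable)` summing to 1, or a list of triples keyed by contextual
#'   criterion id.
#' @param drift per-criterion systematic re-test shift in score points
#'   (single value recycled).
#' @param noise per-criterion SD of the re-test perturbation; the draw is
#'   rounded half away from zero before clamping, so a +/-0.5 perturbation
#'   can move a score.
#' @param seed integer seed for all generators derived from this spec.
#' @return an object of class `panel_spec`.
#' @export
panel_spec <- function(counts = c(policymaker = 5, evaluator = 7,
                                  clinician = 5, patient_representative = 1),
                       weight_location = c(
                         severity = 4.6, urgency = 4.7, efficacy = 4.4,
                         safety = 4.3, internal_validity = 4.0,
                         therapeutic_benefit = 4.3, external_validity = 3.7,
                         plausibility = 3.6),
                       weight_dispersion = c(
                         severity = 0.6, urgency = 0.6, efficacy = 0.6,
                         safety = 0.6, internal_validity = 0.7,
                         therapeutic_benefit = 0.6, external_validity = 0.7,
                         plausibility = 0.7),
                       score_location = 3, score_dispersion = 1,
                       contextual_probs = c(favourable = 0.5, neutral = 0.3,
                                            unfavourable = 0.2),
                       drift = 0, noise = 0, seed = 1L) {
  if (is.null(names(counts)) || !all(names(counts) %in% panel_profiles()))
    stop_mcda("counts must be named with the four panel profiles")
  if (any(counts < 0) || sum(counts) < 1)
    stop_mcda("profile counts must be >= 0 with total >= 1")
  check_probs <- function(p, where) {
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop_mcda(where, " must be a non-negative triple summing to 1")
  }
  if (is.list(contextual_probs)) lapply(names(contextual_probs), function(id)
    check_probs(contextual_probs[[id]], paste0("contextual_probs$", id)))
  else check_probs(contextual_probs, "contextual_probs")
  chk_disp <- function(d) if (any(unlist(d) < 0))
    stop_mcda("dispersions must be >= 0")
  chk_disp(weight_dispersion); chk_disp(score_dispersion); chk_disp(noise)
  structure(
    list(counts = counts, weight_location = weight_location,
         weight_dispersion = weight_dispersion,
         score_location = score_location,
         score_dispersion = score_dispersion,
         contextual_probs = contextual_probs,
         drift = drift, noise = noise, seed = as.integer(seed)),
    class = "panel_spec"
  )
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf("<panel_spec> %d panellists (%s); seed %d\n", sum(x$counts),
              paste(sprintf("%d %s", x$counts, names(x$counts)),
                    collapse = ", "), x$seed))
  invisible(x)
}

spec_roster <- function(spec) {
  n <- sum(spec$counts)
  data.frame(panellist_id = sprintf("p%02d", seq_len(n)),
             profile = rep(names(spec$counts), spec$counts))
}

profile_param <- function(x, profile, ids, what) {
  if (is.list(x) && !is.null(names(x)) && any(names(x) %in% panel_profiles())) {
    if (is.null(x[[profile]]))
      stop_mcda(what, " has no entry for profile '", profile, "'")
    return(resolve_param(x[[profile]], ids, what))
  }
  resolve_param(x, ids, what)
}

#' Simulate panel weights
#'
#' Draws each panellist's raw 1..5 importance weight for every core
#' criterion from the mean-calibrated discretized truncated normal defined
#' by the spec (per-profile locations honoured when given). Bit-reproducible
#' under a fixed seed.
#'
#' @param spec a [panel_spec()].
#' @param framework an [mcda_framework()]; its core criteria define the
#'   weight vector.
#' @return list with `weights` (long data.frame: `panellist_id`, `profile`,
#'   `criterion_id`, `weight`) and `roster`.
#' @export
simulate_weights <- function(spec, framework = default_framework("final")) {
  stopifnot(inherits(spec, "panel_spec"))
  roster <- spec_roster(spec)
  ids <- core_ids(framework)
  with_local_seed(substream_seed(spec$seed, "weights"), {
    rows <- lapply(seq_len(nrow(roster)), function(i) {
      loc <- profile_param(spec$weight_location, roster$profile[i], ids,
                           "weight_location")
      disp <- profile_param(spec$weight_dispersion, roster$profile[i], ids,
                            "weight_dispersion")
      data.frame(panellist_id = roster$panellist_id[i],
                 profile = roster$profile[i], criterion_id = ids,
                 weight = vapply(ids, function(id)
                   draw_discnorm(1, loc[id], disp[id], 1L, 5L), 0))
    })
    list(weights = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         roster = roster)
  })
}

#' Simulate a case assessment
#'
#' Draws quantitative scores on every core criterion's scale (dichotomous
#' criteria Bernoulli between their endpoints) and contextual ratings from
#' the spec's probability triples, for every panellist on the roster.
#'
#' @param spec a [panel_spec()].
#' @param framework an [mcda_framework()].
#' @param case_id case identifier for the generated assessment.
#' @return an [mcda_assessment()].
#' @export
simulate_assessment <- function(spec, framework = default_framework("final"),
                                case_id = "synthetic-case") {
  stopifnot(inherits(spec, "panel_spec"))
  roster <- spec_roster(spec)
  ids <- core_ids(framework)
  scales <- core_scales(framework)
  loc <- resolve_param(spec$score_location, ids, "score_location")
  disp <- resolve_param(spec$score_dispersion, ids, "score_dispersion")
  ctx <- contextual_ids(framework)
  with_local_seed(substream_seed(spec$seed, "assessment"), {
    quant <- do.call(rbind, lapply(ids, function(id) {
      sc <- scales[[id]]
      score <- if (sc$dichotomous) {
        p <- min(max((loc[id] - sc$minimum) / (sc$maximum - sc$minimum), 0), 1)
        sample(c(sc$minimum, sc$maximum), nrow(roster), replace = TRUE,
               prob = c(1 - p, p))
      } else {
        draw_discnorm(nrow(roster), loc[id], disp[id], sc$minimum, sc$maximum)
      }
      data.frame(panellist_id = roster$panellist_id, criterion_id = id,
                 score = as.integer(score))
    }))
    qual <- if (length(ctx)) do.call(rbind, lapply(ctx, function(id) {
      p <- if (is.list(spec$contextual_probs)) {
        if (is.null(spec$contextual_probs[[id]]))
          stop_mcda("contextual_probs missing criterion '", id, "'")
        spec$contextual_probs[[id]]
      } else spec$contextual_probs
      data.frame(panellist_id = roster$panellist_id, criterion_id = id,
                 rating = sample(QUAL_LEVELS, nrow(roster), replace = TRUE,
                                 prob = p))
    })) else NULL
    mcda_assessment(case_id, quant, qual, framework,
                    description = "synthetic case assessment")
  })
}

#' Simulate a re-test of an assessment
#'
#' Perturbs the base assessment's quantitative scores by a per-criterion
#' systematic drift plus integer-rounded noise, clamped to each criterion's
#' scale (and snapped to the nearer endpoint for dichotomous criteria).
#' With zero drift and zero noise the re-test is identical to the base.
#' Contextual ratings are carried over unchanged.
#'
#' @param spec a [panel_spec()] (its `drift`, `noise` and `seed` are used).
#' @param base an [mcda_assessment()] generated on the same framework.
#' @return an [mcda_assessment()] with the same case id.
#' @export
simulate_retest <- function(spec, base) {
  stopifnot(inherits(spec, "panel_spec"), inherits(base, "mcda_assessment"))
  framework <- base$framework
  ids <- core_ids(framework)
  scales <- core_scales(framework)
  drift <- resolve_param(spec$drift, ids, "drift")
  noise <- resolve_param(spec$noise, ids, "noise")
  quant <- base$quant
  with_local_seed(substream_seed(spec$seed, "retest"), {
    for (i in seq_len(nrow(quant))) {
      id <- quant$criterion_id[i]
      sc <- scales[[id]]
      eps <- if (noise[id] > 0) round_half_away(stats::rnorm(1, 0, noise[id]))
             else 0
      v <- quant$score[i] + drift[id] + eps
      v <- min(max(v, sc$minimum), sc$maximum)
      if (sc$dichotomous) {
        mid <- (sc$minimum + sc$maximum) / 2
        v <- if (v > mid) sc$maximum
             else if (v < mid) sc$minimum
             else quant$score[i]  # equidistant: keep the original endpoint
      }
      quant$score[i] <- as.integer(round(v))
    }
    mcda_assessment(base$case_id, quant, base$qual, framework,
                    description = paste(base$description, "(re-test)"))
  })
}
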