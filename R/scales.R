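#' Scoring scale for a quantitative criterion
#'
#' A categorical scoring scale with integer anchors, from a worst score
#' (`minimum`) to a best score (`maximum`). The default core-model scale runs
#' 0 (worst, low or none) to 5 (best or high). A dichotomous scale admits only
#' its two endpoints (used for all-or-nothing judgements such as biological
#' plausibility, scored 0 = not plausible or 5 = plausible).
#'
#' @param minimum integer, worst score.
#' @param maximum integer, best score; must exceed `minimum`.
#' @param dichotomous logical; if `TRUE` only `minimum` and `maximum` are
#'   admissible.
#' @param anchor_labels character(2), free-text labels for the two endpoints.
#' @return an object of class `scoring_scale`.
#' @examples
#' scoring_scale(0, 5)
#' scoring_scale(0, 5, dichotomous = TRUE)
#' @export
scoring_scale <- function(minimum = 0L, maximum = 5L, dichotomous = FALSE,
                          anchor_labels = c("worst", "best")) {
  if (!is.numeric(minimum) || !is.numeric(maximum) ||
      minimum != as.integer(minimum) || maximum != as.integer(maximum))
    stop_mcda("scale endpoints must be integers")
  if (minimum >= maximum)
    stop_mcda("scale minimum (", minimum, ") must be below maximum (",
              maximum, ")")
  structure(
    list(minimum = as.integer(minimum), maximum = as.integer(maximum),
         dichotomous = isTRUE(dichotomous),
         anchor_labels = as.character(anchor_labels)),
    class = "scoring_scale"
  )
}

#' Admissible scores on a scale
#'
#' @param scale a [scoring_scale()].
#' @return integer vector of admissible raw scores.
#' @export
admissible_scores <- function(scale) {
  stopifnot(inherits(scale, "scoring_scale"))
  if (scale$dichotomous) c(scale$minimum, scale$maximum)
  else seq.int(scale$minimum, scale$maximum)
}

check_score <- function(score, scale, what = "score") {
  if (!is.numeric(score) || length(score) != 1L || is.na(score) ||
      score != as.integer(score))
    stop_mcda(what, " must be a single integer")
  if (score < scale$minimum || score > scale$maximum)
    stop_mcda(what, " ", score, " outside scale ", scale$minimum, "..",
              scale$maximum)
  if (scale$dichotomous && !(score %in% c(scale$minimum, scale$maximum)))
    stop_mcda(what, " ", score, " not admissible on a dichotomous scale {",
              scale$minimum, ", ", scale$maximum, "}")
  invisible(as.integer(score))
}

#' @export
print.scoring_scale <- function(x, ...) {
  kind <- if (x$dichotomous) sprintf("{%d, %d} (dichotomous)",
                                     x$minimum, x$maximum)
          else sprintf("%d..%d", x$minimum, x$maximum)
  cat(sprintf("<scoring_scale> %s  [%s -> %s]\n", kind,
              x$anchor_labels[1], x$anchor_labels[2]))
  invisible(x)
}

#' Standardize a raw score onto [0, 1]
#'
#' Maps a raw categorical score onto the unit interval relative to its scale:
#' `S = (score - minimum) / (maximum - minimum)`. On the default 0..5 scale
#' this is `score / 5`, so a top score always standardizes to 1 and the value
#' estimate built from such scores attains its ceiling of 1.
#'
#' @param score integer raw score, admissible on `scale`.
#' @param scale a [scoring_scale()].
#' @return the standardized score, a fraction in \[0, 1\].
#' @examples
#' standardize_score(5, scoring_scale(0, 5)) # 1
#' standardize_score(3, scoring_scale(0, 5)) # 0.6
#' @export
standardize_score <- function(score, scale) {
  check_score(score, scale)
  (score - scale$minimum) / (scale$maximum - scale$minimum)
}
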