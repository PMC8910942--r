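#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mcda <- function(..., class = "mcda_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Round half away from zero
#'
#' Base [round()] rounds half to even; score-perturbation noise instead uses
#' the convention that a half always moves away from zero, so a +/-0.5
#' perturbation can change an integer score.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Derive a per-purpose RNG substream seed from one global seed, so that each
# generator draws from its own stream and adding a call to one generator does
# not perturb the draws of another. Kept below 2^31 (R integers are 32-bit).
substream_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647)
}

# Evaluate expr under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Integer display percentage (round half to even, base round); exact fraction
# is always carried alongside wherever this is used.
display_pct <- function(frac) round(100 * frac)

#' Panellist profiles
#'
#' The four professional profiles a panellist can be classified under:
#' policymakers, evaluators, clinicians and patient representatives.
#'
#' @return character vector of the four profile labels.
#' @export
panel_profiles <- function() {
  c("policymaker", "evaluator", "clinician", "patient_representative")
}
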