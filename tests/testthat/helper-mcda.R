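# Shared test fixtures and independent oracles.

final_fw <- default_framework("final")
pilot_fw <- default_framework("pilot")

equal_weights <- function(framework = final_fw) {
  ids <- core_ids(framework)
  stats::setNames(rep(1 / length(ids), length(ids)), ids)
}

# a tiny two-criterion framework for hand-checkable arithmetic
tiny_fw <- mcda_framework(
  "tiny",
  core = list(criterion("a", kind = "quantitative"),
              criterion("b", kind = "quantitative")),
  contextual = list(criterion("ctx", kind = "qualitative"))
)

make_scores <- function(panellist_id, values, framework = final_fw) {
  ids <- core_ids(framework)
  data.frame(panellist_id = panellist_id, criterion_id = ids,
             score = as.integer(values))
}

norm_weight_list <- function(weights_df) {
  lapply(split(weights_df, weights_df$panellist_id), function(w)
    normalize_rating_scale(raw_weights(w$panellist_id[1],
                                       stats::setNames(w$weight,
                                                       w$criterion_id))))
}

# Independent brute-force Wilcoxon signed-rank oracle: enumerates all 2^n
# sign assignments of the observed (mid)ranks of the nonzero differences.
brute_signed_rank_p <- function(d) {
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0) return(1)
  r <- rank(abs(nz))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_dist <- as.numeric(signs %*% r)
  w_obs <- sum(r[nz > 0])
  p_lo <- mean(w_dist <= w_obs + 1e-9)
  p_hi <- mean(w_dist >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}
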