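# Shared fixtures for the test suite. Everything is built in code; the only
# files read are the reference-table transcriptions shipped in extdata.

# Deterministic representative of the condition-1 cell (simple complexity,
# 3 IVs, small/small coefficients): both coefficient levels at the midpoint
# of their U[0.1, 0.3] range.
cond1_midpoint <- function() {
  coefficient_set(rep(0.2, 3), rep(0.2, 2), 1, condition_from_id(1))
}

# A tiny replication_summary-like list for criterion unit tests.
fake_summary <- function(lp, up, above, rt2 = 0.7, rl2 = 0.65,
                         rn2 = NULL) {
  list(lp = lp, up = up, above = above, rt2 = rt2, rl2 = rl2,
       rn2_values = rn2)
}

# Exact Likert cell probabilities P(X = v) for x ~ N(3, 1), by convention.
cell_probs <- function(method) {
  cuts <- if (method == "round") c(-Inf, 1.5, 2.5, 3.5, 4.5, Inf)
          else c(-Inf, 1, 2, 3, 4, Inf)
  diff(pnorm(cuts, mean = 3, sd = 1))
}
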