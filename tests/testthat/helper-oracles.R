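# Independent brute-force oracles used across test files.

# Mann-Whitney U by direct pair counting: number of (a_i, b_j) pairs with
# a_i > b_j, plus half a count per tie.
brute_force_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Exact two-sided Mann-Whitney p-value by enumerating all assignments of
# the pooled sample to the two groups (no ties assumed).
brute_force_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(i) brute_force_u(pooled[i], pooled[-i]))
  u_obs <- brute_force_u(a, b)
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# A minimal two-food table built in code, for tests that do not need the
# shipped survey fixture.
tiny_food_table <- function() {
  as_food_table(data.frame(
    food = c("staple", "leafy"),
    conc_mean = c(0.02, 0.05), conc_std = c(0.01, 0.04),
    conc_median = c(0.015, 0.03), conc_p90 = c(0.05, 0.12),
    intake_mean = c(100, 50), intake_std = c(40, 30),
    intake_median = c(90, 40), intake_p90 = c(160, 100)
  ))
}
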