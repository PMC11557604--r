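# Independent oracles used across tests.

# Exact per-element inclusion probabilities under sequential weighted
# sampling without replacement (weights renormalized after each draw),
# by exhaustive enumeration of all ordered draw sequences.
enum_inclusion_probs <- function(w, k) {
  n <- length(w)
  probs <- numeric(n)
  recurse <- function(remaining, chosen, p) {
    if (length(chosen) == k) {
      probs[chosen] <<- probs[chosen] + p
      return(invisible())
    }
    wr <- w[remaining] / sum(w[remaining])
    for (j in seq_along(remaining))
      recurse(remaining[-j], c(chosen, remaining[j]), p * wr[j])
  }
  recurse(seq_len(n), integer(0), 1)
  probs
}

# Expected number of distinct cases drawn in m uniform with-replacement
# draws from a pool of size N.
expected_distinct <- function(N, m) N * (1 - ((N - 1) / N)^m)

# Simulate records directly from the log-link binomial model.
simulate_from_glm <- function(beta, n_per_sample) {
  completeness <- stats::runif(2 * n_per_sample, 0, 100)
  sample_lab <- rep(c("A", "B"), each = n_per_sample)
  eta <- beta[1] + beta[2] * (sample_lab == "B") + beta[3] * completeness
  p <- pmin(exp(eta), 1)
  data.frame(sample = sample_lab, completeness = completeness,
             trauma = stats::rbinom(2 * n_per_sample, 1, p))
}

# Small fast config for harness tests.
tiny_config <- function(...) {
  experiment_config(n_per_sample = 100, scenarios = 40, iterations = 5,
                    seed = 42, glm_draws = 500, ...)
}
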