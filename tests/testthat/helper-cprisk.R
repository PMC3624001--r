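# Small builders shared across the suite.

make_impacts <- function(a, r, label = NULL, id = NULL) {
  impact_data(a, r, label = label, impact_id = id)
}

# 4-score dataset whose ROC sweep is easy to enumerate by hand:
# positives score 3 and 1, negatives score 2 and 0.
tiny_scored <- function() {
  list(scores = c(3, 1, 2, 0), labels = c(1L, 1L, 0L, 0L))
}

# random labelled scores with ties, for estimator-equivalence loops
random_scored <- function(n = 40) {
  labels <- c(1L, 0L, rbinom(n - 2, 1, 0.4)) # both classes guaranteed
  scores <- sample(round(rnorm(n), 1))       # rounding induces ties
  list(scores = scores, labels = labels)
}

paper_beta <- c(-10.2, 0.0433, 0.000873, -0.000000920)
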