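# brute-force oracles for the evaluation statistics

# all-pairs concordance count, ties worth one half
naive_auroc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  total <- 0
  for (xi in x) total <- total + sum(xi > y) + 0.5 * sum(xi == y)
  total / (length(x) * length(y))
}

# O(m*n) DeLong structural components
naive_delong_components <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)),
                numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)),
                numeric(1))
  list(theta = mean(v10), v10 = v10, v01 = v01)
}
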