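# Independent oracles: brute-force normal-equations OLS and an exhaustive
# grid maximizer for overall desirability. Both are deliberately naive and
# share no code with the fitting/optimization paths they check.

# model-matrix columns built by explicit arithmetic
oracle_columns <- function(coded, terms) {
  cols <- matrix(0, nrow(coded), length(terms))
  for (j in seq_along(terms)) {
    tm <- terms[j]
    cols[, j] <- if (grepl("\\^2$", tm)) {
      i <- as.integer(substr(tm, 2, 2)); coded[, i]^2
    } else if (grepl(":", tm)) {
      p <- strsplit(tm, ":")[[1]]
      coded[, as.integer(substr(p[1], 2, 2))] *
        coded[, as.integer(substr(p[2], 2, 2))]
    } else {
      coded[, as.integer(substr(tm, 2, 2))]
    }
  }
  colnames(cols) <- terms
  cols
}

# OLS by solving the normal equations directly
ols_oracle <- function(coded, y, terms = quadratic_terms()) {
  X <- cbind("(Intercept)" = 1, oracle_columns(coded, terms))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  stats::setNames(drop(beta), colnames(X))
}

# R^2 of the oracle fit
ols_oracle_r2 <- function(coded, y, terms = quadratic_terms()) {
  X <- cbind(1, oracle_columns(coded, terms))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  1 - sum((y - X %*% beta)^2) / sum((y - mean(y))^2)
}

# exhaustive-grid maximum of overall desirability with predicted min/max
# anchors; returns the best D and its coded point
grid_desirability_oracle <- function(models, n = 101L, literal = FALSE) {
  ax <- seq(-1, 1, length.out = n)
  gr <- as.matrix(expand.grid(ax, ax, ax))
  D <- rep(1, nrow(gr))
  for (m in models) {
    y <- predict_response(m, gr, literal = literal)
    d <- (y - min(y)) / (max(y) - min(y))
    D <- D * d
  }
  D <- D^(1 / length(models))
  i <- which.max(D)
  list(D = D[i], coded = gr[i, ])
}

# absolute-difference expectation (expect_equal tolerances are relative)
expect_within <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual - expected), tol)
}

# the packaged design's coded matrix in standard order (frozen expectation)
expected_bbd17 <- function() {
  rbind(
    c(-1, -1, 0), c(1, -1, 0), c(-1, 1, 0), c(1, 1, 0),
    c(-1, 0, -1), c(1, 0, -1), c(-1, 0, 1), c(1, 0, 1),
    c(0, -1, -1), c(0, 1, -1), c(0, -1, 1), c(0, 1, 1),
    matrix(0, 5, 3)
  )
}
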