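# Independent brute-force oracles. These deliberately re-derive each
# quantity along a different code path than the package (explicit loops,
# direct definitions) so agreement is informative.

# Lorenz points by direct cumulative summation
oracle_lorenz <- function(values) {
  n <- length(values)
  v <- sort(values)
  cbind(p = (0:n) / n, f = c(0, cumsum(v)) / sum(v))
}

# One tangent-construction split: recompute the final-segment slope from
# the Lorenz points themselves and count sorted positions above the
# x-intercept.
oracle_loubar <- function(values, tol = 1e-9) {
  n <- length(values)
  pts <- oracle_lorenz(values)
  slope <- (pts[n + 1, "f"] - pts[n, "f"]) / (pts[n + 1, "p"] - pts[n, "p"])
  if (slope <= 1 + tol) {
    return(list(flat = TRUE, selected = seq_len(n)))
  }
  x_star <- 1 - 1 / slope
  positions <- (1:n) / n
  n_sel <- sum(positions > x_star)
  # replicate the package's documented tie policy independently
  boundary <- sort(values, decreasing = TRUE)[n_sel]
  above <- which(values > boundary)
  fill <- which(values == boundary)[seq_len(n_sel - sum(values > boundary))]
  list(flat = FALSE, selected = sort(c(above, fill)))
}

# Full iterated levelling built only on oracle_loubar
oracle_assign_levels <- function(values, min_cells = 1) {
  level <- rep(NA_integer_, length(values))
  remaining <- which(values > 0)
  ell <- 0L
  repeat {
    ell <- ell + 1L
    sp <- oracle_loubar(values[remaining])
    level[remaining[sp$selected]] <- ell
    remaining <- remaining[-sp$selected]
    if (sp$flat || length(remaining) == 0) break
    if (length(remaining) < min_cells) {
      ell <- ell + 1L
      level[remaining] <- ell
      remaining <- integer(0)
      break
    }
  }
  level[values == 0] <- ell
  level
}

# Per-edge bucketing of flows into a level matrix, one edge at a time
oracle_level_matrix <- function(flows, levels_by_id) {
  L <- max(unlist(levels_by_id))
  M <- matrix(0, L, L)
  for (r in seq_len(nrow(flows))) {
    i <- levels_by_id[[flows$origin[r]]]
    j <- levels_by_id[[flows$destination[r]]]
    M[i, j] <- M[i, j] + flows$weight[r]
  }
  M / sum(M)
}

# Tri-diagonal trace by explicit double loop
oracle_phi <- function(T_mat) {
  L <- nrow(T_mat)
  total <- 0
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (abs(i - j) <= 1) total <- total + T_mat[i, j]
    }
  }
  total
}

# Pearson r by the closed covariance formula (no stats::cor)
oracle_pearson_r <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# OLS R^2 via the normal equations, solved directly
oracle_ols_r2 <- function(y, X) {
  X1 <- cbind(1, as.matrix(X))
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  fitted <- X1 %*% beta
  1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
}

# random normalized matrix supported only on the tri-diagonal band
random_band_matrix <- function(L) {
  M <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (abs(i - j) <= 1) M[i, j] <- stats::runif(1)
    }
  }
  M / sum(M)
}

# tiny deterministic fixture network used across files
fixture_network <- function() {
  cells <- data.frame(
    id = c("a", "b", "c", "d"),
    x = c(0, 1, 0, 5),
    y = c(0, 0, 1, 5),
    population = c(100, 50, 30, 10)
  )
  flows <- data.frame(
    origin = c("a", "a", "b", "c", "d"),
    destination = c("b", "c", "a", "a", "a"),
    weight = c(10, 5, 8, 4, 2)
  )
  trip_network(flows, cells)
}
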