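test_that("level matrix buckets flows and normalizes to 1", {
  net <- fixture_network()
  a <- assign_levels(cell_outflows(net))
  T_mat <- level_flow_matrix(net, a)
  expect_equal(sum(T_mat), 1)
  lev <- stats::setNames(a$level, a$id)
  expect_equal(unclass(T_mat)[seq_len(nrow(T_mat)), seq_len(ncol(T_mat))],
               unclass(oracle_level_matrix(net$flows, as.list(lev))),
               ignore_attr = TRUE)

  # scaling all flows leaves the normalized matrix unchanged
  scaled <- net
  scaled$flows$weight <- scaled$flows$weight * 7
  expect_equal(level_flow_matrix(scaled, a), T_mat)
})

test_that("random generated networks match the per-edge bucketing oracle", {
  withr::local_seed(31)
  net <- generate_city(city_config(grid_side = 6, noise_cv = 0.4, seed = 8))
  a <- assign_levels(cell_outflows(net))
  T_mat <- level_flow_matrix(net, a)
  o <- oracle_level_matrix(net$flows,
                           as.list(stats::setNames(a$level, a$id)))
  expect_equal(unclass(T_mat), unclass(o), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("flow-hierarchy reproduces hand-evaluated matrices", {
  T3 <- matrix(c(0.2, 0, 0.2, 0, 0.2, 0, 0.2, 0, 0.2), 3, 3)
  expect_equal(flow_hierarchy(T3), 0.6)
  expect_equal(flow_hierarchy(matrix(1)), 1)

  # band-only support gives exactly 1
  band <- matrix(c(0.3, 0.2, 0, 0.1, 0.2, 0.1, 0, 0.05, 0.05), 3, 3)
  expect_equal(flow_hierarchy(band), 1)

  expect_error(flow_hierarchy(matrix(c(0.5, 0.1, 0.1, 0.1), 2, 2)),
               class = "flowhier_validation_error")
})

test_that("metric is 1 iff off-band mass vanishes, on random matrices", {
  withr::local_seed(41)
  for (rep in 1:40) {
    L <- sample(2:10, 1)
    B <- random_band_matrix(L)
    expect_equal(flow_hierarchy(B), 1, tolerance = 1e-12)
    expect_equal(flow_hierarchy(B), oracle_phi(B), tolerance = 1e-12)

    M <- matrix(runif(L^2), L, L)
    M <- M / sum(M)
    off <- sum(M) - oracle_phi(M)
    if (off > 1e-9) expect_lt(flow_hierarchy(M), 1)
    expect_equal(flow_hierarchy(M), oracle_phi(M), tolerance = 1e-12)
    expect_gte(flow_hierarchy(M), 0)
  }
})

test_that("uniform null closed form matches the uniform matrix for L = 1..20", {
  expect_equal(uniform_null_phi(1), 1)
  expect_equal(uniform_null_phi(2), 1)
  for (L in 1:20) {
    U <- matrix(1 / L^2, L, L)
    expect_equal(flow_hierarchy(U), uniform_null_phi(L))
  }
  expect_error(uniform_null_phi(0), class = "flowhier_domain_error")
})

test_that("rewired null reproduces the hand outer product and preserves marginals", {
  T3 <- matrix(c(0.2, 0, 0.2, 0, 0.2, 0, 0.2, 0, 0.2), 3, 3)
  null <- rewired_null(T3)
  expect_equal(
    null$T_h,
    matrix(c(0.16, 0.08, 0.16, 0.08, 0.04, 0.08, 0.16, 0.08, 0.16), 3, 3)
  )
  expect_equal(null$phi_h, 0.68)

  # a rank-one matrix is a fixed point
  r <- c(0.5, 0.3, 0.2)
  c_ <- c(0.1, 0.6, 0.3)
  P <- outer(r, c_)
  expect_equal(rewired_null(P)$T_h, P)

  # marginals preserved on random matrices, and raw counts allowed
  withr::local_seed(43)
  for (rep in 1:30) {
    L <- sample(2:12, 1)
    M <- matrix(rexp(L^2), L, L)
    null_raw <- rewired_null(M)
    expect_equal(rowSums(null_raw$T_h), rowSums(M), tolerance = 1e-12)
    expect_equal(colSums(null_raw$T_h), colSums(M), tolerance = 1e-12)
    Mn <- M / sum(M)
    expect_equal(rewired_null(Mn)$phi_h, null_raw$phi_h, tolerance = 1e-12)
  }
})

test_that("star city yields two levels and a fully banded matrix", {
  # one dominant hub exchanging with minor ring cells that do not exchange
  # among themselves: exactly two levels arise, so all flow is on-band
  n_ring <- 8
  cells <- data.frame(
    id = c("hub", sprintf("r%d", 1:n_ring)),
    x = c(0, cos(2 * pi * (1:n_ring) / n_ring)),
    y = c(0, sin(2 * pi * (1:n_ring) / n_ring))
  )
  flows <- rbind(
    data.frame(origin = "hub", destination = sprintf("r%d", 1:n_ring),
               weight = 10),
    data.frame(origin = sprintf("r%d", 1:n_ring), destination = "hub",
               weight = 2)
  )
  res <- city_phi(trip_network(flows, cells))
  expect_equal(res$L, 2)
  expect_equal(res$phi, 1)
  expect_equal(res$phi_uniform, 1)
})

test_that("flat city degenerates to a single level with metric 1", {
  n <- 5
  cells <- data.frame(id = sprintf("f%d", 1:n),
                      x = rep(1:n, 1), y = rep(0, n))
  pairs <- expand.grid(o = cells$id, d = cells$id,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$o != pairs$d, ]
  flows <- data.frame(origin = pairs$o, destination = pairs$d, weight = 1)
  res <- city_phi(trip_network(flows, cells))
  expect_equal(res$L, 1)
  expect_equal(res$phi, 1)
  expect_equal(res$phi_uniform, 1)
})

test_that("the flow-hierarchy is invariant under flow rescaling", {
  net <- generate_city(city_config(grid_side = 6, seed = 2))
  res <- city_phi(net)
  scaled <- net
  scaled$flows$weight <- scaled$flows$weight * 1234.5
  expect_equal(city_phi(scaled)$phi, res$phi)
  expect_equal(city_phi(scaled)$phi_rewired, res$phi_rewired)
})

test_that("tidy and glance summarize a hierarchy result consistently", {
  res <- city_phi(generate_city(city_config(grid_side = 6, seed = 4)))
  td <- tidy(res)
  expect_equal(nrow(td), res$L)
  expect_equal(sum(td$n_cells), nrow(res$assignment))
  expect_equal(sum(td$outflow_share), 1, tolerance = 1e-12)
  gl <- glance(res)
  expect_equal(gl$phi, res$phi)
  expect_equal(gl$phi_uniform, (3 * gl$L - 2) / gl$L^2)
})
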