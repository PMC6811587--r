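two_cells <- function() {
  data.frame(id = c("A", "B"), x = c(0, 1), y = c(0, 0),
             population = c(10, 20))
}

test_that("with a single destination the whole production goes there", {
  ot <- c(A = 5, B = 3)
  for (net in list(
    gravity_flows(two_cells(), ot),
    radiation_flows(two_cells(), ot),
    pwo_flows(two_cells(), ot)
  )) {
    expect_equal(nrow(net$flows), 2)
    expect_equal(net$flows$weight[net$flows$origin == "A"], 5)
    expect_equal(net$flows$weight[net$flows$origin == "B"], 3)
  }
})

test_that("gravity splits by the closed-form deterrence ratio", {
  cells <- data.frame(id = c("o", "m", "f"), x = c(0, 1, 2), y = 0,
                      population = c(1, 1, 1))
  ot <- c(o = 1, m = 0, f = 0)
  net <- gravity_flows(cells, ot,
                       model_config("gravity", deterrence_scale = 1))
  w <- stats::setNames(net$flows$weight, net$flows$destination)
  expect_equal(unname(w["m"] / w["f"]), exp(-1) / exp(-2))
  expect_equal(sum(w), 1)

  # beta reweights destinations by mass^beta
  cells$population <- c(1, 2, 2)
  net2 <- gravity_flows(cells, ot,
                        model_config("gravity", mass_exponent = 2,
                                     deterrence_scale = 1))
  w2 <- stats::setNames(net2$flows$weight, net2$flows$destination)
  expect_equal(unname(w2["m"] / w2["f"]), exp(-1) / exp(-2))
})

test_that("gravity with huge range approaches pure mass-proportional allocation", {
  withr::local_seed(51)
  n <- 12
  cells <- data.frame(id = sprintf("g%d", 1:n), x = runif(n, 0, 5),
                      y = runif(n, 0, 5), population = rlnorm(n, 3))
  ot <- stats::setNames(rep(1, n), cells$id)
  net <- gravity_flows(cells, ot,
                       model_config("gravity", deterrence_scale = 1e9))
  w1 <- net$flows$weight[net$flows$origin == "g1"]
  d1 <- net$flows$destination[net$flows$origin == "g1"]
  m <- stats::setNames(cells$population, cells$id)
  expect_equal(w1, unname(m[d1] / sum(m[d1])), tolerance = 1e-6)
})

test_that("all three models satisfy the production constraint exactly", {
  withr::local_seed(53)
  n <- 30
  cells <- data.frame(id = sprintf("c%d", 1:n), x = runif(n, 0, 10),
                      y = runif(n, 0, 10), population = rlnorm(n, 4))
  ot <- stats::setNames(rexp(n, 1 / 50), cells$id)
  for (net in list(
    gravity_flows(cells, ot, model_config("gravity", mass_exponent = 1.5)),
    gravity_flows(cells, ot,
                  model_config("gravity", deterrence = "power",
                               deterrence_scale = 2)),
    radiation_flows(cells, ot),
    pwo_flows(cells, ot)
  )) {
    got <- cell_outflows(net)
    expect_equal(stats::setNames(got$outflow, got$id), ot[got$id],
                 tolerance = 1e-10)
    expect_true(all(net$flows$weight > 0))
    expect_false(any(net$flows$origin == net$flows$destination))
  }
})

test_that("radiation weights match the direct intervening-mass formula", {
  # masses 1/1/1 on a line at 0, 1, 2: from the origin, the near cell has
  # s = 0 and the far cell s = 1
  cells <- data.frame(id = c("o", "m", "f"), x = c(0, 1, 2), y = 0,
                      population = c(1, 1, 1))
  ot <- c(o = 6, m = 0, f = 0)
  net <- radiation_flows(cells, ot)
  w <- stats::setNames(net$flows$weight, net$flows$destination)
  # unnormalized: near 1/(1*2) = 0.5, far 1/((1+1)(1+1+1)) = 1/6
  expect_equal(unname(w["m"] / w["f"]), 0.5 / (1 / 6))
  expect_equal(unname(sum(w)), 6)

  # random instance against a brute-force oracle
  withr::local_seed(57)
  n <- 25
  rc <- data.frame(id = sprintf("r%d", 1:n), x = runif(n, 0, 8),
                   y = runif(n, 0, 8), population = rlnorm(n, 2))
  ot2 <- stats::setNames(rep(10, n), rc$id)
  net2 <- radiation_flows(rc, ot2)
  d <- as.matrix(stats::dist(rc[, c("x", "y")]))
  m <- rc$population
  for (i in sample(n, 5)) {
    raw <- vapply(seq_len(n), function(j) {
      if (j == i) return(0)
      s <- sum(m[d[i, ] < d[i, j]]) - m[i]
      m[i] * m[j] / ((m[i] + s) * (m[i] + m[j] + s))
    }, numeric(1))
    want <- 10 * raw / sum(raw)
    got <- stats::setNames(
      net2$flows$weight[net2$flows$origin == rc$id[i]],
      net2$flows$destination[net2$flows$origin == rc$id[i]]
    )
    expect_equal(unname(got[rc$id[-i]]), want[-i], tolerance = 1e-12)
  }
})

test_that("relabelling cells leaves the radiation flow multiset unchanged", {
  withr::local_seed(59)
  n <- 15
  cells <- data.frame(id = sprintf("c%d", 1:n), x = runif(n), y = runif(n),
                      population = rlnorm(n))
  ot <- stats::setNames(rep(1, n), cells$id)
  net <- radiation_flows(cells, ot)

  perm <- sample(n)
  relab <- cells[perm, ]
  relab$id <- sprintf("z%d", 1:n)
  ot2 <- stats::setNames(rep(1, n), relab$id)
  net2 <- radiation_flows(relab, ot2)
  expect_equal(sort(net2$flows$weight), sort(net$flows$weight),
               tolerance = 1e-12)
})

test_that("opportunity model matches symmetry and the circle-counting oracle", {
  # symmetric unit square with equal masses: the two side destinations are
  # exchangeable and split equally; the diagonal destination sees more
  # intervening mass inside its circle and receives strictly less
  sq <- data.frame(id = c("a", "b", "c", "d"),
                   x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
                   population = rep(2, 4))
  ot <- stats::setNames(rep(9, 4), sq$id)
  net <- pwo_flows(sq, ot)
  from_a <- net$flows[net$flows$origin == "a", ]
  w <- stats::setNames(from_a$weight, from_a$destination)
  expect_equal(unname(w["b"]), unname(w["c"]))
  expect_lt(w["d"], w["b"])
  expect_equal(unname(sum(w)), 9)

  withr::local_seed(61)
  n <- 30
  rc <- data.frame(id = sprintf("p%d", 1:n), x = runif(n, 0, 10),
                   y = runif(n, 0, 10), population = rlnorm(n, 2))
  ot2 <- stats::setNames(rexp(n, 0.1), rc$id)
  net2 <- pwo_flows(rc, ot2)
  d <- as.matrix(stats::dist(rc[, c("x", "y")]))
  m <- rc$population
  M <- sum(m)
  for (i in sample(n, 5)) {
    raw <- vapply(seq_len(n), function(j) {
      if (j == i) return(0)
      S_ji <- sum(m[d[j, ] < d[j, i]]) # includes j, excludes i
      m[j] * (1 / S_ji - 1 / M)
    }, numeric(1))
    raw[raw < 0] <- 0
    want <- unname(ot2[rc$id[i]]) * raw / sum(raw)
    got <- stats::setNames(
      net2$flows$weight[net2$flows$origin == rc$id[i]],
      net2$flows$destination[net2$flows$origin == rc$id[i]]
    )
    full <- stats::setNames(rep(0, n), rc$id)
    full[names(got)] <- got
    expect_equal(unname(full[rc$id[-i]]), want[-i], tolerance = 1e-12)
  }
})

test_that("allocation errors name the offending origins", {
  cells <- data.frame(id = c("A", "B"), x = c(0, 1), y = 0,
                      population = c(1, 0))
  expect_error(
    gravity_flows(cells, c(A = 1, B = 1), masses = c(0, 0)),
    class = "flowhier_allocation_error"
  )
})

test_that("model runs are deterministic", {
  net <- generate_city(city_config(grid_side = 6, seed = 9))
  ofl <- cell_outflows(net)
  r1 <- model_phi(net$cells, ofl, model_config("gravity"))
  r2 <- model_phi(net$cells, ofl, model_config("gravity"))
  expect_identical(r1$phi, r2$phi)
  expect_identical(r1$T, r2$T)
})
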