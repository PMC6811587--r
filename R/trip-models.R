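#' Trip-distribution model configuration
#'
#' Bundles the knobs of the model-based flow generators. All three models
#' are production-constrained: per-origin outgoing totals are taken as given
#' and only the destination split is modeled.
#'
#' @param model One of `"gravity"`, `"radiation"`, `"pwo"`.
#' @param mass_exponent Destination-mass exponent `beta` for the gravity
#'   model (1 = linear, 2 = quadratic; ignored by the other models).
#' @param deterrence Gravity distance-deterrence family, `"exponential"`
#'   (`exp(-d / scale)`) or `"power"` (`d^-scale`).
#' @param deterrence_scale Deterrence scale: km for the exponential form (default 2),
#'   the dimensionless exponent for the power form. Must be positive.
#' @return A list of class `model_config`.
#' @export
model_config <- function(model = c("gravity", "radiation", "pwo"),
                         mass_exponent = 1,
                         deterrence = c("exponential", "power"),
                         deterrence_scale = 2) {
  model <- match.arg(model)
  deterrence <- match.arg(deterrence)
  if (!is.numeric(mass_exponent) || mass_exponent < 0) {
    abort_domain("`mass_exponent` must be >= 0.")
  }
  check_positive_scalar(deterrence_scale, "deterrence_scale")
  structure(
    list(
      model = model,
      mass_exponent = mass_exponent,
      deterrence = deterrence,
      deterrence_scale = deterrence_scale
    ),
    class = "model_config"
  )
}

# Pairwise Euclidean distances on the planar km coordinates. Distinct cells
# at identical coordinates get a tiny positive floor so deterrence and
# circle constructions stay defined.
cell_distances <- function(cells) {
  d <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    warning("Distinct cells share coordinates; flooring their distance at 1e-9 km.")
    d[d == 0] <- 1e-9
    diag(d) <- 0
  }
  d
}

# Shared plumbing: validate inputs, align out-trips to the cell table,
# resolve masses (population if present, otherwise the out-trips).
prepare_model_inputs <- function(cells, out_trips, masses = NULL) {
  cells <- validate_cells(cells)
  if (nrow(cells) < 2) abort_domain("Need at least two cells.")
  if (is.data.frame(out_trips)) {
    out_trips <- stats::setNames(out_trips$outflow, out_trips$id)
  }
  o <- unname(out_trips[cells$id])
  if (anyNA(o) || any(o < 0)) {
    abort_domain("`out_trips` must cover every cell with a non-negative value.")
  }
  if (is.null(masses)) {
    masses <- if (!is.null(cells$population)) cells$population else o
  }
  m <- as.numeric(masses)
  if (length(m) != nrow(cells) || anyNA(m) || any(m < 0)) {
    abort_domain("Masses must be non-negative, one per cell.")
  }
  if (sum(m > 0) < 2) {
    abort_allocation("Need at least two cells with positive mass.")
  }
  list(cells = cells, out = o, mass = m)
}

# Turn an allocation-probability matrix (rows = origins, diagonal ignored)
# into a production-constrained trip_network: row i is scaled to O_i.
allocation_to_network <- function(P, cells, out) {
  diag(P) <- 0
  rs <- rowSums(P)
  bad <- which(out > 0 & rs <= 0)
  if (length(bad) > 0) {
    abort_allocation(sprintf(
      "Origin(s) with positive out-trips but no positive-weight destination: %s.",
      paste(cells$id[bad], collapse = ", ")
    ))
  }
  scale <- ifelse(rs > 0, out / rs, 0)
  T_ij <- P * scale
  keep <- which(T_ij > 0, arr.ind = TRUE)
  flows <- tibble::tibble(
    origin = cells$id[keep[, 1]],
    destination = cells$id[keep[, 2]],
    weight = T_ij[keep]
  )
  trip_network(flows, cells)
}

#' Gravity-model trip flows
#'
#' Production-constrained gravity allocation: origin `i` distributes its
#' out-trips `O_i` over destinations in proportion to
#' `m_j^beta * f(d_ij)`, where `f` is an exponential (`exp(-d / lambda)`) or
#' power (`d^-gamma`) deterrence. Per-origin totals are matched exactly and
#' the diagonal is excluded. Raising `beta` from 1 (linear) towards 2
#' (quadratic) strengthens the pull of high-mass cells and concentrates
#' flows among top hotspots.
#'
#' @param cells Cell table (`id`, `x`, `y`, optional `population`).
#' @param out_trips Per-cell out-trip totals: a named vector or an
#'   `id`/`outflow` tibble such as [cell_outflows()] returns.
#' @param config A [model_config()] (its `model` field is ignored here).
#' @param masses Optional explicit masses; defaults to `population` when the
#'   cell table has it, otherwise to the out-trips.
#' @return A [trip_network()] of model flows.
#' @export
gravity_flows <- function(cells, out_trips, config = model_config(),
                          masses = NULL) {
  inp <- prepare_model_inputs(cells, out_trips, masses)
  d <- cell_distances(inp$cells)
  f <- switch(config$deterrence,
    exponential = exp(-d / config$deterrence_scale),
    power = {
      fd <- d^(-config$deterrence_scale)
      fd[!is.finite(fd)] <- 0
      fd
    }
  )
  P <- sweep(f, 2, inp$mass^config$mass_exponent, `*`)
  allocation_to_network(P, inp$cells, inp$out)
}

# For each row-origin r, the total mass strictly closer to r than each
# other cell j (excluding r itself and j). Vectorized per row via the
# sorted cumulative mass.
intervening_mass <- function(d, mass) {
  n <- nrow(d)
  s <- matrix(0, n, n)
  for (r in seq_len(n)) {
    x <- d[r, ]
    ord <- order(x)
    cm <- c(0, cumsum(mass[ord]))
    # number of cells with distance strictly below x[j]
    k <- findInterval(x, sort(x), left.open = TRUE)
    s[r, ] <- cm[k + 1] - mass[r] # r itself (d = 0) is always inside
  }
  diag(s) <- 0
  s
}

#' Radiation-model trip flows
#'
#' Parameter-free trip model: the attractiveness of destination `j` as seen
#' from origin `i` is discounted by the intervening mass `s_ij`, the total
#' mass strictly inside the circle of radius `d_ij` centered on `i`
#' (excluding `i` and `j`; distance ties are left outside the circle):
#' \deqn{p_{ij} \propto \frac{m_i m_j}{(m_i + s_{ij})(m_i + m_j + s_{ij})}.}
#' Flows are renormalized per origin so out-trip totals are matched exactly
#' (this absorbs the usual finite-size correction into the production
#' constraint).
#'
#' @inheritParams gravity_flows
#' @return A [trip_network()] of model flows.
#' @export
radiation_flows <- function(cells, out_trips, masses = NULL) {
  inp <- prepare_model_inputs(cells, out_trips, masses)
  d <- cell_distances(inp$cells)
  s <- intervening_mass(d, inp$mass)
  m <- inp$mass
  P <- outer(m, m) / ((m + s) * (outer(m, m, `+`) + s))
  P[!is.finite(P)] <- 0
  allocation_to_network(P, inp$cells, inp$out)
}

# S[j, i]: total mass within the circle centered on destination j of radius
# d(j, i) — inclusive of j (distance 0), exclusive of i (strict inequality
# leaves the boundary, hence i itself, outside).
destination_circle_mass <- function(d, mass) {
  n <- nrow(d)
  S <- matrix(0, n, n)
  for (j in seq_len(n)) {
    x <- d[j, ]
    ord <- order(x)
    cm <- c(0, cumsum(mass[ord]))
    k <- findInterval(x, sort(x), left.open = TRUE)
    S[j, ] <- cm[k + 1]
  }
  S
}

#' Population-weighted-opportunities trip flows
#'
#' Destination `j` attracts trips from origin `i` with weight
#' `m_j * (1 / S_ji - 1 / M)`, where `S_ji` is the total mass within the
#' circle centered on `j` of radius `d_ji` (inclusive of `j`, exclusive of
#' `i`) and `M` is the total mass. The circle-inclusion convention is a
#' known ambiguity of this model family; the one implemented here is stated
#' in the formula above. Per-origin totals are matched exactly.
#'
#' @inheritParams gravity_flows
#' @return A [trip_network()] of model flows.
#' @export
pwo_flows <- function(cells, out_trips, masses = NULL) {
  inp <- prepare_model_inputs(cells, out_trips, masses)
  M <- sum(inp$mass)
  d <- cell_distances(inp$cells)
  S <- destination_circle_mass(d, inp$mass)
  # P[i, j] = m_j (1/S_ji - 1/M)
  W <- ifelse(S > 0, 1 / S - 1 / M, 0)
  P <- t(W) # rows become origins
  P <- sweep(P, 2, inp$mass, `*`)
  P[P < 0] <- 0
  allocation_to_network(P, inp$cells, inp$out)
}

#' Model-based flow-hierarchy estimate
#'
#' Generates model flows from cell masses and out-trip totals, then runs the
#' standard hotspot/flow-hierarchy pipeline on them. This is the device for
#' asking whether the hierarchical organization of a city can be recovered
#' from aggregated trip-distribution models given only per-cell outflows.
#'
#' @inheritParams gravity_flows
#' @param config A [model_config()]; its `model` field selects the
#'   generator.
#' @param min_cells Passed to [assign_levels()].
#' @return A `hierarchy_result` (see [city_phi()]) with an extra `model`
#'   element recording the configuration.
#' @export
model_phi <- function(cells, out_trips, config = model_config(),
                      min_cells = 1, masses = NULL) {
  net <- switch(config$model,
    gravity = gravity_flows(cells, out_trips, config, masses),
    radiation = radiation_flows(cells, out_trips, masses),
    pwo = pwo_flows(cells, out_trips, masses)
  )
  res <- city_phi(net, min_cells = min_cells)
  res$model <- config
  res
}
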