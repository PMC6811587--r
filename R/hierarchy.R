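#' Level-to-level trip flow matrix
#'
#' Buckets every directed flow by the hotspot levels of its endpoints and
#' normalizes by the total number of inter-cell trips, so entries sum to 1
#' and matrices are comparable across cities of different size. Entry
#' `T[i, j]` is the share of all trips that go from a level-`i` cell to a
#' level-`j` cell.
#'
#' @param network A [trip_network()].
#' @param assignment A `hotspot_levels` tibble from [assign_levels()]
#'   covering every flow endpoint.
#' @return An `L x L` matrix of class `level_flow_matrix` with entries
#'   summing to 1; `dimnames` are the level indices.
#' @export
level_flow_matrix <- function(network, assignment) {
  stopifnot(inherits(network, "trip_network"),
            inherits(assignment, "hotspot_levels"))
  L <- n_levels(assignment)
  lev <- stats::setNames(assignment$level, assignment$id)

  lo <- unname(lev[network$flows$origin])
  ld <- unname(lev[network$flows$destination])
  if (anyNA(lo) || anyNA(ld)) {
    bad <- unique(c(
      network$flows$origin[is.na(lo)],
      network$flows$destination[is.na(ld)]
    ))
    abort_validation(sprintf(
      "Flow endpoint(s) without a hotspot level: %s.",
      paste(sort(bad), collapse = ", ")
    ))
  }

  T_mat <- matrix(0, L, L, dimnames = list(seq_len(L), seq_len(L)))
  sums <- rowsum(network$flows$weight, group = lo + (ld - 1L) * L)
  T_mat[as.integer(rownames(sums))] <- sums[, 1]
  T_mat <- T_mat / sum(T_mat)
  class(T_mat) <- c("level_flow_matrix", class(T_mat))
  T_mat
}

check_level_matrix <- function(T_mat, tol = 1e-8) {
  if (!is.matrix(T_mat) || nrow(T_mat) != ncol(T_mat)) {
    abort_validation("Level-flow matrix must be square.")
  }
  if (any(T_mat < 0)) {
    abort_validation("Level-flow matrix entries must be non-negative.")
  }
  s <- sum(T_mat)
  if (abs(s - 1) > tol * max(1, abs(s))) {
    abort_validation(sprintf(
      "Level-flow matrix is not normalized (entries sum to %.10g, not 1).", s
    ))
  }
  invisible(T_mat)
}

#' Flow-hierarchy of a level-flow matrix
#'
#' The flow-hierarchy is the tri-diagonal trace of the normalized level-flow
#' matrix: the total share of trips exchanged between same-level or
#' adjacent-level hotspots,
#' \deqn{\Phi = \sum_{i=1}^{L-1} (T_{ii} + T_{i,i+1} + T_{i+1,i}) + T_{LL}.}
#' It equals 1 when all interaction is within the band (tree-like,
#' maximally hierarchical cities) and approaches `(3L - 2)/L^2` when flows
#' are spread uniformly over all level pairs (flat cities). For `L = 1` the
#' band is the whole matrix and the metric is 1 by convention.
#'
#' @param T_mat A normalized square matrix (entries sum to 1 within `tol`).
#' @param tol Relative normalization tolerance (default `1e-8`).
#' @return The flow-hierarchy, a number in `[0, 1]`.
#' @examples
#' T_mat <- matrix(c(0.2, 0, 0.2, 0, 0.2, 0, 0.2, 0, 0.2), 3, 3)
#' flow_hierarchy(T_mat) # 0.6
#' @export
flow_hierarchy <- function(T_mat, tol = 1e-8) {
  check_level_matrix(T_mat, tol = tol)
  L <- nrow(T_mat)
  band <- sum(diag(T_mat))
  if (L > 1) {
    idx <- seq_len(L - 1)
    band <- band +
      sum(T_mat[cbind(idx, idx + 1)]) +
      sum(T_mat[cbind(idx + 1, idx)])
  }
  min(band, 1) # guard against tol-sized overshoot
}

#' Uniform-null flow-hierarchy
#'
#' Closed form of the flow-hierarchy when trips are distributed uniformly
#' over all `L^2` level pairs: the band holds `3L - 2` of the `L^2` equal
#' entries, so \eqn{\Phi_u = (3L - 2) / L^2}.
#'
#' @param L Number of hotspot levels (integer `>= 1`).
#' @return `(3 * L - 2) / L^2`.
#' @examples
#' uniform_null_phi(14) # about 0.20
#' @export
uniform_null_phi <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L < 1 ||
      L != round(L)) {
    abort_domain("`L` must be a single integer >= 1.")
  }
  (3 * L - 2) / L^2
}

#' Marginal-preserving rewired null
#'
#' Rebuilds the level-flow matrix as if level pairings were independent,
#' preserving the empirical distribution of flow over levels: each entry is
#' the product of its row total (outflow of level `i`) and the column share
#' (fraction of inflows into level `j`),
#' \deqn{T^h_{ij} = \left(\sum_k T_{ik}\right)
#'   \frac{\sum_m T_{mj}}{\sum_{mk} T_{mk}}.}
#' Row and column sums are preserved exactly. The flow-hierarchy of this
#' null, `phi_h`, captures what the heterogeneous level-flow distribution
#' alone would produce; the excess of the observed metric over `phi_h`
#' reflects genuine spatial correlation between hotspots. The form is valid
#' on unnormalized count matrices too (the grand total cancels).
#'
#' @param T_mat A square non-negative matrix (normalized or raw counts).
#' @return A list with `T_h` (the null matrix, same normalization as the
#'   input) and `phi_h` (its flow-hierarchy, computed on the normalized
#'   null).
#' @export
rewired_null <- function(T_mat) {
  if (!is.matrix(T_mat) || nrow(T_mat) != ncol(T_mat)) {
    abort_validation("Level-flow matrix must be square.")
  }
  if (any(T_mat < 0)) {
    abort_validation("Level-flow matrix entries must be non-negative.")
  }
  total <- sum(T_mat)
  if (total <= 0) abort_validation("Level-flow matrix has zero total.")
  T_h <- outer(rowSums(T_mat), colSums(T_mat)) / total
  dimnames(T_h) <- dimnames(T_mat)
  list(T_h = T_h, phi_h = flow_hierarchy(T_h / total))
}

#' End-to-end flow-hierarchy of a city
#'
#' Runs the full pipeline on one trip network: per-cell outflows, iterated
#' Loubar level extraction, the normalized level-flow matrix, the
#' flow-hierarchy, and both null models.
#'
#' @param network A [trip_network()].
#' @param min_cells Passed to [assign_levels()].
#' @return An object of class `hierarchy_result`: a list with elements
#'   `phi`, `L`, `phi_uniform`, `phi_rewired`, `T` (the level-flow matrix),
#'   `T_rewired`, `assignment` (the `hotspot_levels` tibble), `level_counts`
#'   and `level_outflow_shares`.
#' @examples
#' city <- generate_city(city_config(grid_side = 8, seed = 1))
#' res <- city_phi(city)
#' glance(res)
#' @export
city_phi <- function(network, min_cells = 1) {
  stopifnot(inherits(network, "trip_network"))
  ofl <- cell_outflows(network)
  assignment <- assign_levels(ofl, min_cells = min_cells)
  T_mat <- level_flow_matrix(network, assignment)
  null <- rewired_null(T_mat)

  counts <- as.integer(table(factor(assignment$level,
                                    levels = seq_len(n_levels(assignment)))))
  shares <- vapply(
    seq_len(n_levels(assignment)),
    function(l) sum(assignment$outflow[assignment$level == l]),
    numeric(1)
  )
  shares <- shares / sum(assignment$outflow)

  structure(
    list(
      phi = flow_hierarchy(T_mat),
      L = n_levels(assignment),
      phi_uniform = uniform_null_phi(n_levels(assignment)),
      phi_rewired = null$phi_h,
      T = T_mat,
      T_rewired = null$T_h,
      assignment = assignment,
      level_counts = counts,
      level_outflow_shares = shares
    ),
    class = "hierarchy_result"
  )
}

#' @export
print.hierarchy_result <- function(x, ...) {
  cat(sprintf(
    "<hierarchy_result> phi = %.4f  (L = %d, uniform null %.4f, rewired null %.4f)\n",
    x$phi, x$L, x$phi_uniform, x$phi_rewired
  ))
  invisible(x)
}

#' Tidy a hierarchy result into per-level rows
#'
#' @param x A `hierarchy_result` from [city_phi()].
#' @param ... Unused.
#' @return A tibble with one row per hotspot level: `level`, `n_cells`,
#'   `outflow_share`, `threshold`.
#' @export
tidy.hierarchy_result <- function(x, ...) {
  thr <- attr(x$assignment, "thresholds")
  length(thr) <- x$L
  tibble::tibble(
    level = seq_len(x$L),
    n_cells = x$level_counts,
    outflow_share = x$level_outflow_shares,
    threshold = thr
  )
}

#' One-row summary of a hierarchy result
#'
#' @param x A `hierarchy_result` from [city_phi()].
#' @param ... Unused.
#' @return A one-row tibble with `phi`, `L`, `phi_uniform`, `phi_rewired`.
#' @export
glance.hierarchy_result <- function(x, ...) {
  tibble::tibble(
    phi = x$phi,
    L = x$L,
    phi_uniform = x$phi_uniform,
    phi_rewired = x$phi_rewired
  )
}
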