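#' Lorenz curve of a non-negative distribution
#'
#' The Lorenz curve is the sorted cumulative distribution: values are sorted
#' ascending and point `k` is `(k/n, sum of the k smallest values / total)`.
#' For cell outflows it shows what share of total outgoing trips the least
#' active fraction of cells holds; perfectly even activity gives the
#' diagonal.
#'
#' @param values Numeric vector of non-negative values, at least one of them
#'   strictly positive.
#' @return A tibble of class `lorenz_curve` with columns `p` (cumulative node
#'   fraction) and `f` (cumulative value fraction), `n + 1` rows starting at
#'   `(0, 0)` and ending at `(1, 1)`.
#' @examples
#' lorenz_curve(c(1, 1, 1, 1))
#' @export
lorenz_curve <- function(values) {
  values <- check_outflow_values(values)
  n <- length(values)
  sorted <- sort(values)
  out <- tibble::tibble(
    p = seq(0, n) / n,
    f = c(0, cumsum(sorted)) / sum(sorted)
  )
  class(out) <- c("lorenz_curve", class(out))
  out
}

check_outflow_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values) || any(values < 0) ||
      any(!is.finite(values))) {
    abort_domain("Values must be non-negative finite numbers.")
  }
  if (sum(values) <= 0) {
    abort_degenerate(
      "All values are zero: the Lorenz construction is undefined."
    )
  }
  values
}

#' Loubar threshold split of a distribution
#'
#' Implements one step of the nonparametric hotspot criterion: the tangent to
#' the Lorenz curve at (1, 1) is extrapolated down to the x-axis, and the
#' cells beyond the intercept are the hotspots. The curve is piecewise
#' linear, so the derivative at (1, 1) is the final segment's slope
#' `s = n * max(values) / sum(values)` and the intercept is `x* = 1 - 1/s`.
#' Hotspots are the cells in sorted positions above `x*`, i.e. the top
#' `n - floor(n * x*)` cells.
#'
#' When the distribution is flat (`s <= 1 + tol`) the tangent coincides with
#' the diagonal, no threshold exists, and all cells are returned as a single
#' group with `flat = TRUE`.
#'
#' Ties at the cut boundary are resolved deterministically: all cells whose
#' value strictly exceeds the boundary value are selected, and remaining
#' slots are filled among boundary-valued cells in input order.
#'
#' @param values Numeric vector of non-negative values (one positive at
#'   least).
#' @param tol Flatness tolerance on the slope (default `1e-9`).
#' @return A list with `threshold` (smallest selected value), `hotspots`
#'   (integer indices into `values`), `slope`, `x_intercept`, and `flat`.
#' @examples
#' loubar_split(c(1, 2, 2, 5, 10)) # selects the 5 and the 10
#' @export
loubar_split <- function(values, tol = 1e-9) {
  values <- check_outflow_values(values)
  n <- length(values)
  s <- n * max(values) / sum(values)

  if (s <= 1 + tol) {
    return(list(
      threshold = min(values),
      hotspots = seq_len(n),
      slope = s,
      x_intercept = NA_real_,
      flat = TRUE
    ))
  }

  x_star <- 1 - 1 / s
  k <- n - floor(n * x_star) # slots above the intercept; always >= 1

  ord_desc <- order(values, decreasing = TRUE) # ties keep input order
  boundary <- values[ord_desc[k]]
  above <- which(values > boundary)
  remaining <- k - length(above)
  at_boundary <- which(values == boundary)
  selected <- sort(c(above, at_boundary[seq_len(remaining)]))

  list(
    threshold = min(values[selected]),
    hotspots = selected,
    slope = s,
    x_intercept = x_star,
    flat = FALSE
  )
}

#' Assign hotspot levels by iterated Loubar thresholding
#'
#' Extracts the full hierarchy of hotspot levels from cell outflows. The
#' Loubar split is applied to the outflow distribution; selected cells become
#' level 1 hotspots and are removed from the distribution, the threshold is
#' recomputed on the remainder to yield level 2, and so on. Iteration stops
#' when the remaining distribution is flat, when fewer than `min_cells` cells
#' remain, or when no positive-outflow cell remains; every cell still
#' unassigned at that point (including zero-outflow cells) lands in the final
#' level `L`.
#'
#' @param outflows A tibble with columns `id` and `outflow` (as produced by
#'   [cell_outflows()]), or a named numeric vector.
#' @param min_cells Minimum number of cells a further iteration needs
#'   (default 1, i.e. iterate to exhaustion).
#' @return A tibble of class `hotspot_levels` with columns `id`, `outflow`,
#'   `level` (1 = most active), carrying attributes `L` (number of levels),
#'   `thresholds` (per-level flow cutoffs) and `zero_cells_in_last_level`
#'   (how many zero-outflow cells were folded into level `L`).
#' @examples
#' ofl <- tibble::tibble(id = letters[1:5], outflow = c(1, 2, 2, 5, 10))
#' assign_levels(ofl)
#' @export
assign_levels <- function(outflows, min_cells = 1) {
  if (is.numeric(outflows)) {
    ids <- names(outflows) %||% as.character(seq_along(outflows))
    outflows <- tibble::tibble(id = ids, outflow = as.numeric(outflows))
  }
  stopifnot(is.data.frame(outflows),
            all(c("id", "outflow") %in% names(outflows)))
  if (min_cells < 1) abort_domain("`min_cells` must be >= 1.")
  check_outflow_values(outflows$outflow)

  ids <- as.character(outflows$id)
  vals <- as.numeric(outflows$outflow)
  level <- rep(NA_integer_, length(vals))
  thresholds <- numeric(0)

  remaining <- which(vals > 0)
  zero_cells <- which(vals == 0)
  ell <- 0L
  repeat {
    ell <- ell + 1L
    split <- loubar_split(vals[remaining])
    sel <- remaining[split$hotspots]
    level[sel] <- ell
    thresholds[ell] <- split$threshold
    remaining <- setdiff(remaining, sel)
    if (split$flat || length(remaining) == 0) {
      break
    }
    if (length(remaining) < min_cells) {
      ell <- ell + 1L
      level[remaining] <- ell
      thresholds[ell] <- min(vals[remaining])
      remaining <- integer(0)
      break
    }
  }

  # zero-outflow cells join the final (least active) level
  L <- ell
  level[zero_cells] <- L

  out <- tibble::tibble(id = ids, outflow = vals, level = level)
  structure(
    out,
    L = L,
    thresholds = thresholds,
    zero_cells_in_last_level = length(zero_cells),
    class = c("hotspot_levels", class(tibble::tibble()))
  )
}

#' Number of hotspot levels in an assignment
#'
#' @param assignment A `hotspot_levels` tibble from [assign_levels()].
#' @return Integer `L >= 1`.
#' @export
n_levels <- function(assignment) {
  stopifnot(inherits(assignment, "hotspot_levels"))
  attr(assignment, "L")
}
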