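#' Construct a trip network
#'
#' A trip network couples a cell table (spatial units with projected planar
#' coordinates in kilometres, and optionally a resident population) with a
#' directed origin--destination flow table. It is the object every analysis
#' stage in flowhier consumes. Intra-cell (self-loop) flows are never stored:
#' rows with `origin == destination` are dropped and counted, matching the
#' convention that only inter-cell trips enter the analysis. Duplicate
#' `(origin, destination)` rows are summed, as weekly-aggregated trip sources
#' naturally produce repeated pairs.
#'
#' Coordinates must already be projected to a planar km system; flowhier does
#' no geographic projection of its own.
#'
#' @param flows A data frame with columns `origin`, `destination`, `weight`
#'   (non-negative trip counts or rates).
#' @param cells A data frame with columns `id`, `x`, `y` and optionally
#'   `population` (non-negative). Ids must be unique.
#' @return An object of class `trip_network`: a list with tibbles `cells`
#'   (`id`, `x`, `y`, optional `population`) and `flows` (`origin`, `destination`,
#'   `weight`), plus attribute `dropped_self_loops` giving the number of
#'   self-loop rows removed.
#' @examples
#' cells <- data.frame(id = c("a", "b"), x = c(0, 1), y = c(0, 0))
#' flows <- data.frame(origin = "a", destination = "b", weight = 5)
#' net <- trip_network(flows, cells)
#' total_flow(net)
#' @export
trip_network <- function(flows, cells) {
  cells <- validate_cells(cells)
  flows <- as.data.frame(flows)
  required <- c("origin", "destination", "weight")
  missing_cols <- setdiff(required, names(flows))
  if (length(missing_cols) > 0) {
    abort_format(sprintf(
      "Flow table is missing column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  flows <- tibble::tibble(
    origin = as.character(flows$origin),
    destination = as.character(flows$destination),
    weight = as.numeric(flows$weight)
  )
  if (anyNA(flows$weight) || any(flows$weight < 0)) {
    abort_format("Flow weights must parse as non-negative finite numbers.")
  }
  if (any(!is.finite(flows$weight))) {
    abort_format("Flow weights must be finite.")
  }

  unknown <- setdiff(
    unique(c(flows$origin, flows$destination)),
    cells$id
  )
  if (length(unknown) > 0) {
    abort_referential(sprintf(
      "Flow endpoint(s) absent from the cell table: %s.",
      paste(sort(unknown), collapse = ", ")
    ))
  }

  self_loops <- flows$origin == flows$destination
  n_dropped <- sum(self_loops)
  flows <- flows[!self_loops, , drop = FALSE]

  # sum duplicate (origin, destination) pairs; rowsum keeps this fast on
  # the dense edge lists the trip models emit
  key <- paste(flows$origin, flows$destination, sep = "\r")
  if (anyDuplicated(key)) {
    sums <- rowsum(flows$weight, group = key, reorder = FALSE)
    first <- !duplicated(key)
    flows <- tibble::tibble(
      origin = flows$origin[first],
      destination = flows$destination[first],
      weight = unname(sums[match(key[first], rownames(sums)), 1])
    )
  }
  flows <- flows[order(flows$origin, flows$destination, method = "radix"), ,
                 drop = FALSE]

  if (nrow(flows) == 0 || sum(flows$weight) <= 0) {
    abort_empty("Network has zero total inter-cell flow.")
  }

  structure(
    list(cells = cells, flows = flows),
    dropped_self_loops = n_dropped,
    class = "trip_network"
  )
}

validate_cells <- function(cells) {
  cells <- as.data.frame(cells)
  required <- c("id", "x", "y")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    abort_format(sprintf(
      "Cell table is missing column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    id = as.character(cells$id),
    x = as.numeric(cells$x),
    y = as.numeric(cells$y)
  )
  if ("population" %in% names(cells)) {
    out$population <- as.numeric(cells$population)
    if (any(out$population < 0, na.rm = TRUE)) {
      abort_format("Cell populations must be non-negative.")
    }
  }
  if (anyDuplicated(out$id)) {
    abort_format("Cell ids must be unique.")
  }
  if (any(!is.finite(out$x)) || any(!is.finite(out$y))) {
    abort_format("Cell coordinates must be finite.")
  }
  out
}

#' @export
print.trip_network <- function(x, ...) {
  cat(sprintf(
    "<trip_network> %d cells, %d directed flows, total flow %.6g\n",
    nrow(x$cells), nrow(x$flows), total_flow(x)
  ))
  if (!is.null(x$cells$population)) {
    cat(sprintf("  total population %.6g\n", sum(x$cells$population)))
  }
  invisible(x)
}

#' Total inter-cell flow of a network
#'
#' @param network A [trip_network()].
#' @return The sum of all directed flow weights (self-loops are never stored).
#' @export
total_flow <- function(network) {
  stopifnot(inherits(network, "trip_network"))
  sum(network$flows$weight)
}

#' Read a trip network from CSV files
#'
#' Edge list columns: `origin,destination,weight`; cell table columns:
#' `id,x,y[,population]`. Self-loop rows are dropped (their count is retained
#' in the `dropped_self_loops` attribute) and duplicate origin--destination
#' rows are summed.
#'
#' @param edge_path Path to the edge-list CSV.
#' @param cells_path Path to the cell-table CSV.
#' @return A [trip_network()].
#' @export
read_trip_network <- function(edge_path, cells_path) {
  edges <- readr::read_csv(edge_path, show_col_types = FALSE,
                           progress = FALSE)
  cells <- readr::read_csv(cells_path, show_col_types = FALSE,
                           progress = FALSE)
  trip_network(edges, cells)
}

#' Write a trip network to CSV files
#'
#' Writes the edge list and cell table at full double precision so that
#' `read_trip_network()` reproduces flows and coordinates exactly.
#'
#' @param network A [trip_network()].
#' @param edge_path Output path for the edge-list CSV.
#' @param cells_path Output path for the cell-table CSV.
#' @return Invisibly, `network`.
#' @export
write_trip_network <- function(network, edge_path, cells_path) {
  stopifnot(inherits(network, "trip_network"))
  if (nrow(network$flows) == 0 || total_flow(network) <= 0) {
    abort_empty("Refusing to write a network with no inter-cell flow.")
  }
  readr::write_csv(network$flows, edge_path, progress = FALSE)
  readr::write_csv(network$cells, cells_path, progress = FALSE)
  invisible(network)
}

#' Per-cell total outgoing flow
#'
#' Hotspot extraction thresholds the number of outgoing trips of every cell;
#' this computes that vector. Cells with no outgoing flows get 0. The sum of
#' all outflows equals the total network flow.
#'
#' @param network A [trip_network()].
#' @return A tibble with columns `id` and `outflow`, in cell-table order.
#' @examples
#' cells <- data.frame(id = c("a", "b", "c"), x = 0:2, y = c(0, 0, 0))
#' flows <- data.frame(origin = c("a", "a", "b"),
#'                     destination = c("b", "c", "c"),
#'                     weight = c(2, 3, 1))
#' cell_outflows(trip_network(flows, cells))
#' @export
cell_outflows <- function(network) {
  stopifnot(inherits(network, "trip_network"))
  out <- network$flows |>
    dplyr::group_by(id = .data$origin) |>
    dplyr::summarise(outflow = sum(.data$weight), .groups = "drop")
  network$cells |>
    dplyr::select("id") |>
    dplyr::left_join(out, by = "id") |>
    dplyr::mutate(outflow = dplyr::coalesce(.data$outflow, 0))
}

#' Coarse-grain a network onto a square grid
#'
#' Maps every cell into the square-grid bin containing its `(x, y)` and
#' re-aggregates flows by bin pair. Bins are half-open `[k*s, (k+1)*s)`
#' anchored at the origin `(0, 0)`; a cell exactly on a boundary goes to the
#' higher-index bin. Flows whose endpoints fall in the same bin become
#' intra-cell and are excluded, so the coarse-grained total flow equals the
#' original total minus same-bin flow. Bin coordinates are bin centers and
#' bin population is the sum of member populations.
#'
#' Coarse-graining at several cell sizes and recomputing the flow-hierarchy
#' is the standard probe of its spatial-scale stability.
#'
#' @param network A [trip_network()].
#' @param cell_size Grid spacing in km (> 0).
#' @return A [trip_network()] on the grid bins.
#' @export
coarse_grain <- function(network, cell_size) {
  stopifnot(inherits(network, "trip_network"))
  check_positive_scalar(cell_size, "cell_size")

  binned <- network$cells |>
    dplyr::mutate(
      bx = floor(.data$x / cell_size),
      by = floor(.data$y / cell_size),
      bin = sprintf("g%d_%d", .data$bx, .data$by)
    )

  new_cells <- binned |>
    dplyr::group_by(.data$bin, .data$bx, .data$by) |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of("population"), sum),
      .groups = "drop"
    ) |>
    dplyr::transmute(
      id = .data$bin,
      x = (.data$bx + 0.5) * cell_size,
      y = (.data$by + 0.5) * cell_size,
      dplyr::across(dplyr::any_of("population"))
    )

  lut <- stats::setNames(binned$bin, binned$id)
  new_flows <- network$flows |>
    dplyr::mutate(
      origin = unname(lut[.data$origin]),
      destination = unname(lut[.data$destination])
    )
  # trip_network() drops newly-diagonal flows and sums duplicates
  trip_network(new_flows, new_cells)
}
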