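#' Correlate the flow-hierarchy with a per-city indicator
#'
#' Measures the association between the flow-hierarchy column and one
#' indicator column three ways: squared Pearson correlation, squared
#' Spearman rank correlation, and the explained variance of a LOESS fit of
#' the indicator on the flow-hierarchy (`1 - RSS/TSS`). Significance stars
#' follow the usual thresholds: one for p < 0.05, two for p < 0.01, three
#' for p < 0.001 (based on the Pearson p-value; the Spearman p-value is
#' reported alongside).
#'
#' Analysis is complete-case per indicator; the number of dropped rows is
#' reported. The LOESS explained variance can be negative for pathological
#' fits; the raw value is kept in `r2_loess` and a floored copy in
#' `r2_loess_clipped`.
#'
#' @param table A data frame with a `phi` column (or another via `phi_col`)
#'   and the indicator column; one row per city.
#' @param indicator Name of the indicator column (string).
#' @param phi_col Name of the flow-hierarchy column (default `"phi"`).
#' @param loess_span LOESS span (default 0.75).
#' @param loess_degree Local polynomial degree (default 1, locally linear;
#'   tricube weights are the LOESS default).
#' @param p_method `"asymptotic"` (t-approximation, default) or
#'   `"permutation"` (seeded permutation p-values, for small samples).
#' @param n_perm Number of permutations when `p_method = "permutation"`.
#' @param perm_seed Seed for the permutation null.
#' @return A list of class `correlation_result` with `r2_pearson`,
#'   `r2_spearman`, `r2_loess`, `r2_loess_clipped`, `p_pearson`,
#'   `p_spearman`, `stars` (0--3), `n_used`, `n_dropped`, `loess_span`,
#'   `loess_degree`, `indicator`, and the fitted data (`data`, `loess_fit`).
#' @examples
#' tab <- tibble::tibble(city = letters[1:10],
#'                       phi = seq(0.5, 0.95, length.out = 10),
#'                       share = seq(10, 55, length.out = 10))
#' correlate(tab, "share")
#' @export
correlate <- function(table, indicator, phi_col = "phi",
                      loess_span = 0.75, loess_degree = 1,
                      p_method = c("asymptotic", "permutation"),
                      n_perm = 9999, perm_seed = 1L) {
  p_method <- match.arg(p_method)
  stopifnot(is.data.frame(table))
  for (col in c(phi_col, indicator)) {
    if (!col %in% names(table)) {
      abort_format(sprintf("Column `%s` not found in the table.", col))
    }
  }
  x <- as.numeric(table[[phi_col]])
  y <- as.numeric(table[[indicator]])
  ok <- stats::complete.cases(x, y)
  n_dropped <- sum(!ok)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 4) {
    abort_domain("Need at least 4 complete (phi, indicator) pairs.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_degenerate("Zero variance in phi or the indicator.")
  }

  r_p <- stats::cor(x, y)
  r_s <- stats::cor(x, y, method = "spearman")

  if (p_method == "asymptotic") {
    p_p <- stats::cor.test(x, y)$p.value
    p_s <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman")$p.value
    )
  } else {
    withr::local_seed(perm_seed)
    perm_p <- function(stat, method) {
      obs <- abs(stats::cor(x, y, method = method))
      null <- replicate(
        n_perm,
        abs(stats::cor(x, sample(y), method = method))
      )
      (1 + sum(null >= obs)) / (n_perm + 1)
    }
    p_p <- perm_p(r_p, "pearson")
    p_s <- perm_p(r_s, "spearman")
  }

  fit <- stats::loess(y ~ x, span = loess_span, degree = loess_degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2_l <- 1 - rss / tss

  stars <- sum(p_p < c(0.05, 0.01, 0.001))

  structure(
    list(
      indicator = indicator,
      r2_pearson = r_p^2,
      r2_spearman = r_s^2,
      r2_loess = r2_l,
      r2_loess_clipped = max(0, r2_l),
      p_pearson = p_p,
      p_spearman = p_s,
      stars = as.integer(stars),
      n_used = length(x),
      n_dropped = n_dropped,
      loess_span = loess_span,
      loess_degree = loess_degree,
      p_method = p_method,
      data = tibble::tibble(phi = x, value = y),
      loess_fit = fit
    ),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result> %s vs phi (n = %d): R2_P = %.3f, R2_S = %.3f, R2_L = %.3f %s\n",
    x$indicator, x$n_used, x$r2_pearson, x$r2_spearman, x$r2_loess,
    strrep("*", x$stars)
  ))
  invisible(x)
}

#' @rdname correlate
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @export
glance.correlation_result <- function(x, ...) {
  tibble::tibble(
    indicator = x$indicator,
    r2_pearson = x$r2_pearson,
    r2_spearman = x$r2_spearman,
    r2_loess = x$r2_loess,
    p_pearson = x$p_pearson,
    p_spearman = x$p_spearman,
    stars = x$stars,
    n_used = x$n_used,
    n_dropped = x$n_dropped
  )
}

#' Explained-variance gain from adding the flow-hierarchy
#'
#' Fits three ordinary-least-squares models of an indicator (each with an
#' intercept): on the flow-hierarchy alone, on the covariates alone, and on
#' covariates plus flow-hierarchy. The gain is the increase in R-squared
#' from adding the flow-hierarchy to the covariate model; because the
#' models are nested, the gain is never negative.
#'
#' @param table A data frame with `phi` (or `phi_col`), the indicator, and
#'   the covariate columns; one row per city.
#' @param indicator Name of the indicator column.
#' @param covariates Character vector of covariate column names.
#' @param phi_col Name of the flow-hierarchy column (default `"phi"`).
#' @return A list of class `multivariate_gain` with `r2_phi_only`,
#'   `r2_covariates_only`, `r2_full`, `gain`, `n_used`, `n_dropped`,
#'   `indicator`, `covariates`, and the three `lm` fits in `fits`.
#' @export
multivariate_gain <- function(table, indicator, covariates,
                              phi_col = "phi") {
  stopifnot(is.data.frame(table), length(covariates) >= 1)
  needed <- c(phi_col, indicator, covariates)
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    abort_format(sprintf(
      "Column(s) not found: %s.", paste(missing_cols, collapse = ", ")
    ))
  }
  dat <- table[needed]
  names(dat)[1] <- ".phi"
  ok <- stats::complete.cases(dat)
  n_dropped <- sum(!ok)
  dat <- dat[ok, , drop = FALSE]
  if (nrow(dat) < length(covariates) + 3) {
    abort_domain("Too few complete cases for the covariate count.")
  }

  bq <- function(v) paste0("`", v, "`")
  full_terms <- c(".phi", bq(covariates))
  X <- stats::model.matrix(
    stats::reformulate(full_terms),
    data = dat
  )
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    rlang::abort(
      sprintf("Design matrix is rank deficient; offending column(s): %s.",
              paste(dropped, collapse = ", ")),
      class = "flowhier_collinearity_error"
    )
  }

  f_phi <- stats::lm(stats::reformulate(".phi", response = bq(indicator)),
                     data = dat)
  f_cov <- stats::lm(stats::reformulate(bq(covariates),
                                        response = bq(indicator)),
                     data = dat)
  f_full <- stats::lm(stats::reformulate(full_terms,
                                         response = bq(indicator)),
                      data = dat)

  r2 <- function(f) summary(f)$r.squared
  structure(
    list(
      indicator = indicator,
      covariates = covariates,
      r2_phi_only = r2(f_phi),
      r2_covariates_only = r2(f_cov),
      r2_full = r2(f_full),
      gain = r2(f_full) - r2(f_cov),
      n_used = nrow(dat),
      n_dropped = n_dropped,
      fits = list(phi_only = f_phi, covariates_only = f_cov, full = f_full)
    ),
    class = "multivariate_gain"
  )
}

#' @export
print.multivariate_gain <- function(x, ...) {
  cat(sprintf(
    "<multivariate_gain> %s (n = %d): R2 phi-only %.3f | covariates %.3f | full %.3f | gain %.3f\n",
    x$indicator, x$n_used, x$r2_phi_only, x$r2_covariates_only,
    x$r2_full, x$gain
  ))
  invisible(x)
}

#' @rdname multivariate_gain
#' @param x A `multivariate_gain`.
#' @param ... Unused.
#' @export
glance.multivariate_gain <- function(x, ...) {
  tibble::tibble(
    indicator = x$indicator,
    r2_phi_only = x$r2_phi_only,
    r2_covariates_only = x$r2_covariates_only,
    r2_full = x$r2_full,
    gain = x$gain,
    n_used = x$n_used
  )
}

#' Rank cities by flow-hierarchy
#'
#' Sorts cities in decreasing order of the flow-hierarchy (ties broken
#' deterministically by city id) and, when a grouping column is given,
#' appends per-group summaries of both the metric and the rank — the
#' device behind continental league tables.
#'
#' @param table A data frame with columns `city` and `phi` (or `phi_col`).
#' @param group_column Optional name of a grouping column (e.g. continent).
#' @param phi_col Name of the flow-hierarchy column (default `"phi"`).
#' @return A list with `ranking` (a tibble with `rank`, `city`, `phi` and
#'   the group column when given) and
#'   `groups` (tibble of per-group mean/sd of phi and rank, or `NULL`).
#' @export
rank_cities <- function(table, group_column = NULL, phi_col = "phi") {
  stopifnot(is.data.frame(table), nrow(table) > 0,
            "city" %in% names(table), phi_col %in% names(table))
  ranking <- tibble::as_tibble(table) |>
    dplyr::rename(phi = dplyr::all_of(phi_col)) |>
    dplyr::arrange(dplyr::desc(.data$phi), .data$city) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1) |>
    dplyr::select(dplyr::all_of(c("rank", "city", "phi", group_column)))

  groups <- NULL
  if (!is.null(group_column)) {
    groups <- ranking |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group_column))) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_phi = mean(.data$phi),
        sd_phi = stats::sd(.data$phi),
        mean_rank = mean(.data$rank),
        sd_rank = stats::sd(.data$rank),
        .groups = "drop"
      ) |>
      dplyr::arrange(dplyr::desc(.data$mean_phi))
  }
  list(ranking = ranking, groups = groups)
}
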