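#' Tidy a signed association into a cell-level tibble
#'
#' One row per off-diagonal cell (1-mode) or per individual-facility cell
#' (2-mode), with observed and expected counts, the standardized residual,
#' and its classification at the association's threshold.
#'
#' @param x A [signed_association].
#' @param ... Unused.
#' @return A tibble with columns `focal`, `partner`, `observed`, `expected`,
#'   `sr`, `signif` (`"positive"`, `"negative"` or `"ns"`).
#' @export
tidy.signed_association <- function(x, ...) {
  rows <- rownames(x$observed)
  cols <- colnames(x$observed)
  grid <- expand.grid(focal = rows, partner = cols,
                      stringsAsFactors = FALSE)
  out <- tibble::tibble(
    focal = grid$focal, partner = grid$partner,
    observed = as.vector(x$observed),
    expected = as.vector(x$expected),
    sr = as.vector(x$sr))
  if (!isTRUE(x$two_mode)) out <- out[out$focal != out$partner, ]
  out$signif <- dplyr::case_when(out$sr > x$threshold ~ "positive",
                                 out$sr < -x$threshold ~ "negative",
                                 TRUE ~ "ns")
  tibble::as_tibble(out)
}

#' One-row summary of a signed association
#'
#' @param x A [signed_association].
#' @param ... Unused.
#' @return A one-row tibble with grand total, threshold, significant-cell
#'   counts and (for 1-mode) positive and negative network densities.
#' @export
glance.signed_association <- function(x, ...) {
  out <- tibble::tibble(
    n = x$n, threshold = x$threshold, method = x$method,
    n_positive_cells = sum(x$positive > 0),
    n_negative_cells = sum(x$negative > 0))
  if (!isTRUE(x$two_mode)) {
    out$positive_density <- net_density(build_graph(x, "positive"))
    out$negative_density <- net_density(build_graph(x, "negative"))
  }
  out
}

#' Tidy a social graph into its node-metrics table
#'
#' @param x A `"social_graph"`.
#' @param ... Passed to [node_metrics()].
#' @return The [node_metrics()] tibble.
#' @export
tidy.social_graph <- function(x, ...) node_metrics(x, ...)

#' One-row summary of a social graph
#'
#' @param x A `"social_graph"`.
#' @param ... Unused.
#' @return A one-row tibble: sign, node and edge counts, density, number of
#'   cutpoints and blocks.
#' @export
glance.social_graph <- function(x, ...) {
  tibble::tibble(
    sign = x$sign,
    nodes = igraph::vcount(x$graph),
    edges = igraph::ecount(x$graph),
    density = net_density(x),
    n_cutpoints = sum(find_cutpoints(x)),
    n_blocks = length(find_blocks(x)$blocks))
}

#' Tidy a stability series
#'
#' @param x A `"stability_series"`.
#' @param ... Unused.
#' @return A tibble of day-pair correlations; consecutive pairs plus a
#'   `first_last` row, distinguished by the `comparison` column.
#' @export
tidy.stability_series <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$series, comparison = "consecutive"),
    tibble::tibble(day_from = x$series$day_from[1],
                   day_to = x$series$day_to[nrow(x$series)],
                   r = x$first_last$r, p = x$first_last$p,
                   comparison = "first_last"))
}

#' One-row summary of a stability series
#'
#' @param x A `"stability_series"`.
#' @param ... Unused.
#' @return A one-row tibble with the mean consecutive correlation, the
#'   first-vs-last correlation, and bookkeeping counts.
#' @export
glance.stability_series <- function(x, ...) {
  tibble::tibble(
    mean_consecutive_r = x$mean_consecutive_r,
    first_last_r = x$first_last$r,
    n_day_pairs = nrow(x$series),
    n_skipped_days = length(x$skipped_days))
}

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, permutations = x$permutations,
                 tail = x$tail, exact = isTRUE(x$exact))
}

#' @export
glance.mantel_result <- function(x, ...) tidy(x)
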