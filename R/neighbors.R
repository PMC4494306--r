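#' Nearest-neighbor pairs from scan coordinates
#'
#' For every visible individual in every scan, finds the conspecific at
#' minimum 2-D Euclidean distance among the other visible individuals of the
#' same scan. The relation is directed (focal -> neighbor) and not symmetric.
#' Distance ties are broken deterministically by the smallest identifier in
#' sorted order. Scans with fewer than two visible located individuals yield
#' no pairs.
#'
#' @param ds A [scan_data] dataset in coordinate mode.
#' @return A tibble of class `"nn_pairs"` with columns `day`, `scan`,
#'   `focal`, `neighbor`, `nnd` (meters).
#' @export
nearest_neighbor_pairs <- function(ds) {
  if (scan_mode(ds) != "coordinate") {
    abort("nearest_neighbor_pairs() needs a coordinate-mode dataset; use from_observed_neighbors()",
          class = "proxnet_mode_error")
  }
  located <- ds[ds$visible & !is.na(ds$x), , drop = FALSE]
  pairs <- dplyr::group_by(tibble::as_tibble(located), .data$day, .data$scan)
  pairs <- dplyr::group_modify(pairs, function(g, key) {
    n <- nrow(g)
    if (n < 2) {
      return(tibble::tibble(focal = character(), neighbor = character(),
                            nnd = numeric()))
    }
    # order candidates by identifier so which.min() lands on the smallest id
    g <- g[order(g$individual), , drop = FALSE]
    d <- as.matrix(stats::dist(cbind(g$x, g$y)))
    diag(d) <- Inf
    idx <- apply(d, 1, which.min)
    tibble::tibble(focal = g$individual,
                   neighbor = g$individual[idx],
                   nnd = d[cbind(seq_len(n), idx)])
  })
  pairs <- dplyr::ungroup(pairs)
  new_nn_pairs(pairs[c("day", "scan", "focal", "neighbor", "nnd")],
               individuals(ds))
}

new_nn_pairs <- function(pairs, individuals) {
  structure(tibble::as_tibble(pairs),
            class = c("nn_pairs", class(tibble::tibble())),
            individuals = individuals)
}

#' Nearest-neighbor pairs from directly recorded neighbors
#'
#' For datasets where the observer noted each focal individual's nearest
#' neighbor rather than coordinates (e.g. video scans). Records whose
#' neighbor is missing (not seen) are skipped. No nearest-neighbor distance
#' is available, so `nnd` is `NA`.
#'
#' @param ds A [scan_data] dataset in neighbor mode.
#' @return A tibble of class `"nn_pairs"`.
#' @export
from_observed_neighbors <- function(ds) {
  recorded <- ds[!is.na(ds$neighbor), , drop = FALSE]
  unknown <- setdiff(recorded$neighbor, individuals(ds))
  if (length(unknown) > 0) {
    abort(paste0("recorded neighbor(s) not in the individual list: ",
                 paste(unknown, collapse = ", ")),
          class = "proxnet_integrity_error")
  }
  new_nn_pairs(
    tibble::tibble(day = recorded$day, scan = recorded$scan,
                   focal = recorded$individual,
                   neighbor = recorded$neighbor,
                   nnd = NA_real_),
    individuals(ds))
}

#' Summary statistics of nearest-neighbor distances
#'
#' @param pairs An `nn_pairs` tibble with `nnd` present.
#' @param sd_type `"population"` (divide by N, the default) or `"sample"`
#'   (divide by N - 1).
#' @return A one-row tibble with `n`, `mean`, `sd`, `min`, `max` in meters.
#' @export
nnd_statistics <- function(pairs, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  nnd <- pairs$nnd
  if (length(nnd) == 0 || all(is.na(nnd))) {
    abort("no nearest-neighbor distances available",
          class = "proxnet_empty_error")
  }
  nnd <- nnd[!is.na(nnd)]
  n <- length(nnd)
  s <- sd(nnd)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  if (n == 1) s <- 0
  tibble::tibble(n = n, mean = mean(nnd), sd = s,
                 min = min(nnd), max = max(nnd))
}

#' Filter nearest-neighbor pairs by distance
#'
#' Applies an NND ceiling so that only close-proximity pairs enter the
#' association analysis, removing the influence of fixed home ranges. The
#' bound is inclusive by default ("a maximum NND of 5 meters"); set
#' `strict = TRUE` for a strict bound ("less than 1 meter").
#'
#' @param pairs An `nn_pairs` tibble with `nnd` present.
#' @param max_nnd Distance ceiling in meters; `Inf` keeps everything.
#' @param strict If `TRUE` keep `nnd < max_nnd`, else `nnd <= max_nnd`.
#' @return The filtered `nn_pairs` tibble.
#' @export
filter_by_nnd <- function(pairs, max_nnd, strict = FALSE) {
  if (is.infinite(max_nnd)) return(pairs)
  keep <- if (strict) pairs$nnd < max_nnd else pairs$nnd <= max_nnd
  keep[is.na(keep)] <- FALSE
  new_nn_pairs(pairs[keep, , drop = FALSE], attr(pairs, "individuals"))
}

#' Build a directed nearest-neighbor count matrix
#'
#' Tallies how often each focal individual (row) had each other individual
#' (column) as its nearest neighbor. The matrix is directed and has a
#' structurally zero diagonal; its grand total is the number of pairs.
#'
#' @param pairs An `nn_pairs` tibble.
#' @param individuals Ordered identifiers fixing the matrix dimensions;
#'   defaults to the individual list attached to `pairs`.
#' @return An integer matrix of class `"nn_matrix"` with `dimnames` set and
#'   attributes `n_pairs` and `individuals`.
#' @export
build_nn_matrix <- function(pairs, individuals = NULL) {
  if (is.null(individuals)) individuals <- attr(pairs, "individuals")
  if (is.null(individuals)) {
    individuals <- sort(unique(c(pairs$focal, pairs$neighbor)))
  }
  stray <- setdiff(c(pairs$focal, pairs$neighbor), individuals)
  if (length(stray) > 0) {
    abort(paste0("pair member(s) not in the individual list: ",
                 paste(stray, collapse = ", ")),
          class = "proxnet_integrity_error")
  }
  m <- matrix(0L, nrow = length(individuals), ncol = length(individuals),
              dimnames = list(individuals, individuals))
  if (nrow(pairs) > 0) {
    tab <- table(factor(pairs$focal, levels = individuals),
                 factor(pairs$neighbor, levels = individuals))
    m[] <- as.integer(tab)
  }
  structure(m, class = c("nn_matrix", class(m)),
            n_pairs = sum(m), individuals = individuals)
}

#' @export
print.nn_matrix <- function(x, ...) {
  cat(sprintf("<nn_matrix> %d individuals, %d nearest-neighbor pairs\n",
              nrow(x), attr(x, "n_pairs")))
  print(unclass(x)[seq_len(min(10, nrow(x))), seq_len(min(10, ncol(x))),
                   drop = FALSE])
  invisible(x)
}
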