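#' Mantel matrix-correlation permutation test
#'
#' Pearson correlation between the corresponding off-diagonal cells of two
#' conforming square matrices, with significance from a permutation null:
#' the rows and columns of `b` are permuted jointly and the correlation
#' recomputed. The default test is one-tailed upper ("is the association
#' stronger than chance?"), with the add-one rule
#' `p = (1 + #permuted r >= observed r) / (1 + permutations)`. With
#' `exact = TRUE` all `n!` joint permutations are enumerated instead and
#' `p = #{r_perm >= r_obs} / n!` (the identity permutation is included, so
#' `p > 0`).
#'
#' @param a,b Square numeric matrices with identical dimensions (and
#'   identical dimnames if set).
#' @param permutations Number of random permutations (ignored when exact).
#' @param seed Optional integer seed for reproducible permutations.
#' @param tail `"upper"` (default), `"lower"`, or `"two"`.
#' @param exact Enumerate all permutations (only feasible for small n).
#' @return A list of class `"mantel_result"`: `r`, `p`, `permutations`,
#'   `tail`, `seed`.
#' @export
mantel_test <- function(a, b, permutations = 10000, seed = NULL,
                        tail = c("upper", "lower", "two"), exact = FALSE) {
  tail <- match.arg(tail)
  a <- unclass_matrix(a); b <- unclass_matrix(b)
  if (!all(dim(a) == dim(b)) || nrow(a) != ncol(a)) {
    abort("matrices must be square with identical dimensions",
          class = "proxnet_integrity_error")
  }
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    abort("matrix labels differ; align individuals first",
          class = "proxnet_integrity_error")
  }
  n <- nrow(a)
  off <- !diag(n)
  va <- a[off]
  if (sd(va) == 0 || sd(b[off]) == 0) {
    abort("a matrix is constant off-diagonal; correlation undefined",
          class = "proxnet_constant_error")
  }
  r_for <- function(perm) {
    vb <- b[perm, perm][off]
    if (sd(vb) == 0) return(NA_real_)
    cor(va, vb)
  }
  r_obs <- cor(va, b[off])

  count_tail <- function(r_perm) {
    r_perm <- r_perm[!is.na(r_perm)]
    switch(tail,
           upper = sum(r_perm >= r_obs),
           lower = sum(r_perm <= r_obs),
           two = sum(abs(r_perm) >= abs(r_obs)))
  }

  if (exact) {
    if (n > 8) {
      abort("exact enumeration limited to n <= 8 (n! permutations)",
            class = "proxnet_size_error")
    }
    perms <- all_permutations(n)
    r_perm <- vapply(perms, r_for, numeric(1))
    p <- count_tail(r_perm) / length(perms)
    nperm <- length(perms)
  } else {
    if (permutations < 99) {
      abort("use at least 99 permutations", class = "proxnet_size_error")
    }
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    r_perm <- vapply(seq_len(permutations),
                     function(i) r_for(sample.int(n)), numeric(1))
    p <- (1 + count_tail(r_perm)) / (1 + permutations)
    nperm <- permutations
  }
  structure(list(r = r_obs, p = p, permutations = nperm, tail = tail,
                 seed = seed, exact = exact),
            class = "mantel_result")
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %.4g (%s-tailed, %d %s)\n",
              x$r, x$p, x$tail, x$permutations,
              if (isTRUE(x$exact)) "exact permutations" else "permutations"))
  invisible(x)
}

#' Day-to-day network stability series
#'
#' Builds one nearest-neighbor count matrix per day, correlates each
#' consecutive day pair (and the first vs the last day) with [mantel_test()],
#' and summarizes stability as the mean of the consecutive-pair correlations
#' (the first-vs-last correlation is excluded from the mean). Daily matrices
#' are symmetrized (`counts + t(counts)`) by default before correlating.
#'
#' @param ds A [scan_data] dataset spanning at least two days.
#' @param max_nnd,strict Optional NND filter applied to each day's pairs
#'   (coordinate mode only); see [filter_by_nnd()].
#' @param symmetrize Correlate symmetrized daily matrices? Default `TRUE`.
#' @param permutations,seed,tail Passed to [mantel_test()].
#' @return An object of class `"stability_series"`: a list with `series`
#'   (tibble of day pairs with r and p), `first_last` (a `mantel_result`),
#'   `mean_consecutive_r`, and `skipped_days`.
#' @export
daily_series <- function(ds, max_nnd = Inf, strict = FALSE,
                         symmetrize = TRUE, permutations = 10000,
                         seed = NULL, tail = "upper") {
  days <- sort(unique(ds$day))
  if (length(days) < 2) {
    abort("need at least 2 days for a stability series",
          class = "proxnet_size_error")
  }
  ids <- individuals(ds)
  mats <- list(); kept_days <- integer(); skipped <- integer()
  for (d in days) {
    day_rows <- ds[ds$day == d, , drop = FALSE]
    if (scan_mode(ds) == "coordinate" && !any(!is.na(day_rows$x))) {
      warn(sprintf("day %d has no located individuals; skipped", d))
      skipped <- c(skipped, d)
      next
    }
    sub <- scan_data(tibble::as_tibble(day_rows), individuals = ids,
                     facilities = facilities(ds), mode = scan_mode(ds),
                     meta = attr(ds, "meta"))
    pairs <- if (scan_mode(ds) == "coordinate") {
      filter_by_nnd(nearest_neighbor_pairs(sub), max_nnd, strict = strict)
    } else {
      from_observed_neighbors(sub)
    }
    if (nrow(pairs) == 0) {
      warn(sprintf("day %d has no nearest-neighbor pairs; skipped", d))
      skipped <- c(skipped, d)
      next
    }
    m <- build_nn_matrix(pairs, individuals = ids)
    m <- unclass_matrix(m)
    if (symmetrize) m <- m + t(m)
    mats[[length(mats) + 1]] <- m
    kept_days <- c(kept_days, d)
  }
  if (length(mats) < 2) {
    abort("fewer than 2 days with pairs; no series possible",
          class = "proxnet_size_error")
  }
  seeds <- if (is.null(seed)) {
    rep(list(NULL), length(mats))
  } else {
    as.list(seed + seq_along(mats) - 1L)
  }
  rows <- purrr::map(seq_len(length(mats) - 1), function(k) {
    mt <- mantel_test(mats[[k]], mats[[k + 1]], permutations = permutations,
                      seed = seeds[[k]], tail = tail)
    tibble::tibble(day_from = kept_days[k], day_to = kept_days[k + 1],
                   r = mt$r, p = mt$p)
  })
  series <- dplyr::bind_rows(rows)
  first_last <- mantel_test(mats[[1]], mats[[length(mats)]],
                            permutations = permutations,
                            seed = seeds[[length(mats)]], tail = tail)
  new_stability_series(series, first_last, skipped)
}

new_stability_series <- function(series, first_last, skipped_days = integer()) {
  structure(list(series = series, first_last = first_last,
                 mean_consecutive_r = mean(series$r),
                 skipped_days = skipped_days),
            class = "stability_series")
}

#' Build a stability series from already-computed correlations
#'
#' For summarizing published day-to-day correlation tables: takes the
#' consecutive-pair correlations (and optionally the first-vs-last
#' correlation) and computes the mean-consecutive-r stability summary used in
#' cross-network comparisons.
#'
#' @param consecutive_r Numeric vector of consecutive day-pair correlations.
#' @param first_last_r Optional first-vs-last-day correlation (excluded from
#'   the mean).
#' @return A `"stability_series"`.
#' @export
stability_from_correlations <- function(consecutive_r, first_last_r = NA) {
  k <- length(consecutive_r)
  series <- tibble::tibble(day_from = seq_len(k), day_to = seq_len(k) + 1L,
                           r = as.numeric(consecutive_r), p = NA_real_)
  fl <- structure(list(r = as.numeric(first_last_r), p = NA_real_,
                       permutations = 0L, tail = "upper", seed = NULL,
                       exact = FALSE),
                  class = "mantel_result")
  new_stability_series(series, fl)
}

#' @export
print.stability_series <- function(x, ...) {
  cat(sprintf(
    "<stability_series> %d consecutive day pairs, mean r = %.3f (first~last r = %.3f)\n",
    nrow(x$series), x$mean_consecutive_r, x$first_last$r))
  invisible(x)
}
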