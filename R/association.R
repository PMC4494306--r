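#' Expected nearest-neighbor counts under the contingency null
#'
#' The null hypothesis is that who is whose nearest neighbor is independent
#' of identity: the expected count for cell (i, j) is the margins product
#' `row_total_i * col_total_j / n`, with totals taken over the off-diagonal
#' cells (the diagonal is structurally zero: nobody is their own neighbor).
#' Because of that structural zero the plain margins product does not exactly
#' conserve the grand total; `method = "ipf"` runs iterative proportional
#' fitting with the diagonal fixed at zero, which does.
#'
#' @param m An [nn_matrix][build_nn_matrix] (or any square count matrix with
#'   zero diagonal).
#' @param method `"margins"` (default, the classic chi-square convention) or
#'   `"ipf"`.
#' @param tol,max_iter IPF convergence controls.
#' @return A numeric matrix of expected counts, zero diagonal.
#' @export
expected_counts <- function(m, method = c("margins", "ipf"),
                            tol = 1e-10, max_iter = 1000) {
  method <- match.arg(method)
  m <- unclass_matrix(m)
  stopifnot(nrow(m) == ncol(m))
  diag(m) <- 0
  n <- sum(m)
  if (n <= 0) {
    abort("count matrix has zero grand total", class = "proxnet_empty_error")
  }
  r <- rowSums(m)
  s <- colSums(m)
  e <- outer(r, s) / n
  diag(e) <- 0
  if (method == "ipf") {
    off <- !diag(nrow(m))
    for (iter in seq_len(max_iter)) {
      rs <- rowSums(e)
      scale_r <- ifelse(rs > 0, r / rs, 0)
      e <- e * scale_r
      cs <- colSums(e)
      e <- sweep(e, 2, ifelse(cs > 0, s / cs, 0), `*`)
      if (max(abs(rowSums(e) - r)) < tol * max(1, n) &&
          max(abs(colSums(e) - s)) < tol * max(1, n)) break
    }
    diag(e) <- 0
  }
  dimnames(e) <- dimnames(m)
  e
}

unclass_matrix <- function(m) {
  a <- attributes(m)
  m <- unclass(m)
  attributes(m) <- a[c("dim", "dimnames")]
  storage.mode(m) <- "double"
  m
}

#' Standardized residuals of a count table
#'
#' `SR = (o - e) / sqrt(e)` cell-wise. Cells with `e = 0` and `o = 0`
#' (including the structural diagonal) give `SR = 0`; `e = 0` with `o > 0`
#' is an error because the residual is undefined there.
#'
#' @param observed,expected Conforming numeric matrices.
#' @return A numeric matrix of standardized residuals.
#' @export
standardized_residuals <- function(observed, expected) {
  observed <- unclass_matrix(observed)
  expected <- unclass_matrix(expected)
  if (!all(dim(observed) == dim(expected))) {
    abort("observed and expected have different dimensions",
          class = "proxnet_integrity_error")
  }
  undef <- which(expected == 0 & observed > 0, arr.ind = TRUE)
  if (nrow(undef) > 0) {
    abort(sprintf(
      "cell (%d, %d): observed = %g but expected = 0; SR undefined",
      undef[1, 1], undef[1, 2], observed[undef[1, 1], undef[1, 2]]),
      class = "proxnet_undefined_cell_error")
  }
  sr <- matrix(0, nrow(observed), ncol(observed),
               dimnames = dimnames(observed))
  ok <- expected > 0
  sr[ok] <- (observed[ok] - expected[ok]) / sqrt(expected[ok])
  sr
}

#' Split standardized residuals into positive and negative weight matrices
#'
#' Cells with `SR > threshold` go into the positive (attraction) matrix with
#' weight `SR`; cells with `SR < -threshold` go into the negative (avoidance)
#' matrix with weight `-SR` (so both matrices are non-negative). Equality at
#' the boundary is non-significant.
#'
#' @param sr A standardized-residual matrix.
#' @param threshold Two-sided significance cut, default 1.96 (p < 0.05).
#' @return A list with non-negative matrices `positive` and `negative` of
#'   disjoint support.
#' @export
sign_split <- function(sr, threshold = 1.96) {
  stopifnot(threshold > 0)
  sr <- unclass_matrix(sr)
  positive <- ifelse(sr > threshold, sr, 0)
  negative <- ifelse(sr < -threshold, -sr, 0)
  dimnames(positive) <- dimnames(negative) <- dimnames(sr)
  list(positive = positive, negative = negative)
}

#' Signed association structure from a nearest-neighbor count matrix
#'
#' Bundles observed counts, expected counts, standardized residuals and the
#' thresholded positive/negative weight matrices into one object — the input
#' for building signed sociograms.
#'
#' @inheritParams expected_counts
#' @param threshold Significance cut on |SR|, default 1.96.
#' @return An object of class `"signed_association"`.
#' @seealso [build_graph()], [tidy.signed_association()]
#' @export
signed_association <- function(m, threshold = 1.96,
                               method = c("margins", "ipf")) {
  method <- match.arg(method)
  observed <- unclass_matrix(m)
  expected <- expected_counts(m, method = method)
  sr <- standardized_residuals(observed, expected)
  split <- sign_split(sr, threshold)
  structure(
    list(individuals = rownames(observed) %||%
           as.character(seq_len(nrow(observed))),
         observed = observed, expected = expected, sr = sr,
         positive = split$positive, negative = split$negative,
         threshold = threshold, n = sum(observed), method = method,
         two_mode = FALSE),
    class = "signed_association")
}

#' 2-mode animal-by-facility affiliation association
#'
#' Cross-tabulates individuals against their recorded nearest facility and
#' applies the same expected-count / standardized-residual / sign-split
#' machinery as the 1-mode analysis (margins product over the full I x F
#' table; there is no structural diagonal).
#'
#' @param ds A [scan_data] dataset with facility records.
#' @param threshold Significance cut on |SR|, default 1.96.
#' @return An object of class `c("affiliation_association",
#'   "signed_association")` whose matrices are individuals x facilities.
#' @export
affiliation_association <- function(ds, threshold = 1.96) {
  recorded <- ds[!is.na(ds$facility) & ds$visible, , drop = FALSE]
  if (nrow(recorded) == 0) {
    abort("no facility records in dataset", class = "proxnet_empty_error")
  }
  observed <- table(factor(recorded$individual, levels = individuals(ds)),
                    factor(recorded$facility, levels = facilities(ds)))
  observed <- matrix(as.numeric(observed), nrow = length(individuals(ds)),
                     dimnames = list(individuals(ds), facilities(ds)))
  n <- sum(observed)
  expected <- outer(rowSums(observed), colSums(observed)) / n
  sr <- standardized_residuals(observed, expected)
  split <- sign_split(sr, threshold)
  structure(
    list(individuals = individuals(ds), facilities = facilities(ds),
         observed = observed, expected = expected, sr = sr,
         positive = split$positive, negative = split$negative,
         threshold = threshold, n = n, method = "margins", two_mode = TRUE),
    class = c("affiliation_association", "signed_association"))
}

#' @export
print.signed_association <- function(x, ...) {
  kind <- if (x$two_mode) "2-mode affiliation" else "1-mode"
  cat(sprintf(
    "<signed_association> %s, n = %d, |SR| > %g: %d positive, %d negative cells\n",
    kind, round(x$n), x$threshold, sum(x$positive > 0), sum(x$negative > 0)))
  invisible(x)
}

#' Simple ratio association index
#'
#' Dyadic association as the frequency of being nearest neighbors divided by
#' the total number of observations of the two individuals:
#' `sri[i, j] = (counts[i, j] + counts[j, i]) / (obs_i + obs_j)`, where
#' `obs_i` is the number of scans in which individual i was observed. The
#' index is symmetric and lies in \[0, 1\]: a dyad that is mutually nearest
#' in every scan scores 1 and a dyad never associated scores 0. When all
#' animals are visible in every scan the denominator is constant, so the
#' index ranks dyads exactly as the symmetrized nearest-neighbor counts do —
#' the reason count matrices can substitute for the index under complete
#' visibility.
#'
#' @param m An [nn_matrix][build_nn_matrix] of directed counts.
#' @param scans_visible Named per-individual observation counts (scans in
#'   which the individual was visible), e.g. from [count_scans_visible()].
#' @return A symmetric numeric matrix of simple ratio indices, zero diagonal.
#' @export
simple_ratio_index <- function(m, scans_visible) {
  m <- unclass_matrix(m)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  if (!is.null(names(scans_visible))) {
    missing_ids <- setdiff(ids, names(scans_visible))
    if (length(missing_ids) > 0) {
      abort(paste0("scans_visible missing individual(s): ",
                   paste(missing_ids, collapse = ", ")),
            class = "proxnet_integrity_error")
    }
    scans_visible <- scans_visible[ids]
  }
  denom <- outer(scans_visible, scans_visible, `+`)
  zero <- denom == 0 & upper.tri(denom)
  if (any(zero)) {
    warn(sprintf(
      "%d dyad(s) have no observations; their index is set to 0", sum(zero)))
  }
  x <- m + t(m)
  sri <- ifelse(denom > 0, x / denom, 0)
  diag(sri) <- 0
  dimnames(sri) <- list(ids, ids)
  sri
}

#' Per-individual visible scan counts
#'
#' @param ds A [scan_data] dataset.
#' @return A named integer vector: number of scans each individual was
#'   visible in, in dataset individual order.
#' @export
count_scans_visible <- function(ds) {
  vis <- ds[ds$visible, , drop = FALSE]
  tab <- table(factor(vis$individual, levels = individuals(ds)))
  setNames(as.integer(tab), individuals(ds))
}
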