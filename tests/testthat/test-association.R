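test_that("expected counts follow the margins formula and IPF conserves margins", {
  # uniform 4x4 with all off-diagonal counts 5: every e = 15*15/60 = 3.75
  u <- matrix(5, 4, 4); diag(u) <- 0
  dimnames(u) <- list(letters[1:4], letters[1:4])
  e <- expected_counts(u)
  expect_equal(e[upper.tri(e) | lower.tri(e)], rep(3.75, 12))
  expect_equal(diag(e), rep(0, 4), ignore_attr = TRUE)

  # margins-product oracle, coded independently cell by cell
  withr::local_seed(21)
  for (rep in 1:20) {
    m <- random_count_matrix(5)
    e <- expected_counts(m)
    n <- sum(m)
    for (i in 1:5) {
      for (j in 1:5) {
        want <- if (i == j) 0 else sum(m[i, ]) * sum(m[, j]) / n
        expect_equal(e[i, j], want)
      }
    }
    # IPF variant reproduces both margins (and hence the grand total)
    # exactly despite the structural-zero diagonal
    e_ipf <- expected_counts(m, method = "ipf")
    expect_equal(rowSums(e_ipf), rowSums(m), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(colSums(e_ipf), colSums(m), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_lt(abs(sum(m - e_ipf)), 1e-9 * sum(m) + 1e-10)
  }

  zero <- matrix(0, 3, 3)
  expect_error(expected_counts(zero), class = "proxnet_empty_error")
})

test_that("standardized residuals match (o-e)/sqrt(e) and the chi-square identity", {
  e <- matrix(4, 2, 2)
  expect_equal(standardized_residuals(e, e), matrix(0, 2, 2))
  expect_equal(standardized_residuals(matrix(9, 1, 1), matrix(4, 1, 1))[1, 1],
               2.5)

  # sum of squared SRs over a full I x F table equals Pearson's chi-square
  withr::local_seed(8)
  for (rep in 1:20) {
    tab <- matrix(rpois(12, 9) + 1, 3, 4)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sr <- standardized_residuals(tab, e)
    chisq <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(sum(sr^2), unname(chisq$statistic))
  }

  # square off-diagonal case against an independent double-loop computation
  for (rep in 1:5) {
    m <- random_count_matrix(6)
    sr <- standardized_residuals(m, expected_counts(m))
    acc <- 0
    n <- sum(m)
    for (i in 1:6) {
      for (j in setdiff(1:6, i)) {
        eij <- sum(m[i, ]) * sum(m[, j]) / n
        acc <- acc + (m[i, j] - eij)^2 / eij
      }
    }
    expect_equal(sum(sr^2), acc)
  }

  expect_error(
    standardized_residuals(matrix(c(0, 1, 0, 0), 2, 2), matrix(0, 2, 2)),
    "SR undefined", class = "proxnet_undefined_cell_error")
})

test_that("sign_split thresholds strictly and yields disjoint non-negative supports", {
  sr <- matrix(c(0, 1.96, -3, 2.5, 0, -1.96, 0.5, -2.01, 0), 3, 3,
               byrow = TRUE)
  split <- sign_split(sr)
  # equality at the boundary is non-significant on both sides
  expect_equal(split$positive[1, 2], 0)
  expect_equal(split$negative[2, 3], 0)
  # negative residuals are made positive in the negative matrix
  expect_equal(split$negative[1, 3], 3)
  expect_equal(split$negative[3, 2], 2.01)
  expect_equal(split$positive[2, 1], 2.5)
  expect_true(all(split$positive >= 0) && all(split$negative >= 0))
  expect_equal(sum(split$positive > 0 & split$negative > 0), 0)

  # sub-threshold everywhere -> both zero
  small <- sign_split(matrix(runif(9, -1, 1), 3, 3))
  expect_equal(sum(small$positive) + sum(small$negative), 0)

  # raising the threshold never adds edges
  withr::local_seed(12)
  sr2 <- matrix(rnorm(100, 0, 2), 10, 10)
  lo <- sign_split(sr2, 1.96)
  hi <- sign_split(sr2, 2.58)
  expect_true(all((hi$positive > 0) <= (lo$positive > 0)))
  expect_true(all((hi$negative > 0) <= (lo$negative > 0)))
})

test_that("signed_association is equivariant under relabeling of individuals", {
  withr::local_seed(30)
  m <- random_count_matrix(6)
  a <- signed_association(m)
  perm <- sample(6)
  mp <- m[perm, perm]
  ap <- signed_association(mp)
  expect_equal(ap$sr, a$sr[perm, perm])
  expect_equal(ap$positive, a$positive[perm, perm])
})

test_that("simple ratio index is maximal for constant companions and ranks like counts", {
  # dyad mutually nearest in all 100 scans
  m <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  m["A", "B"] <- m["B", "A"] <- 100
  sri <- simple_ratio_index(m, c(A = 100, B = 100))
  expect_equal(sri["A", "B"], 1)

  # never neighbors -> 0
  m0 <- matrix(0, 2, 2, dimnames = dimnames(m))
  expect_equal(simple_ratio_index(m0, c(A = 50, B = 50))["A", "B"], 0)

  # with every animal visible in every scan, the index ranking equals the
  # symmetrized count ranking
  withr::local_seed(14)
  ds <- random_scan_dataset(n_ind = 6, days = 2, scans = 20)
  counts <- build_nn_matrix(nearest_neighbor_pairs(ds))
  sri2 <- simple_ratio_index(counts, count_scans_visible(ds))
  sym <- counts + t(counts)
  up <- upper.tri(sym)
  expect_equal(rank(sri2[up]), rank(sym[up]))
  expect_true(all(sri2 >= 0) && all(sri2 <= 1))

  expect_warning(simple_ratio_index(m0, c(A = 0, B = 0)), "no observations")
})

test_that("affiliation association flags planted facility preference and passes the chi-square oracle", {
  facs <- c("Feed", "Drink", "Perch")
  withr::local_seed(9)
  df <- tidyr::expand_grid(day = 1:2, scan = 1:30,
                           individual = sprintf("Hen%d", 1:5))
  df$facility <- sample(facs, nrow(df), replace = TRUE)
  df$facility[df$individual == "Hen1"] <- "Feed"    # always at the feeder
  a <- affiliation_association(scan_data(df))
  expect_true(a$two_mode)
  expect_gt(a$positive["Hen1", "Feed"], 0)
  expect_equal(sum(a$sr^2),
               unname(suppressWarnings(
                 stats::chisq.test(a$observed, correct = FALSE))$statistic))

  # perfectly uniform facility use -> nothing significant
  df2 <- tidyr::expand_grid(day = 1, scan = 1:30,
                            individual = sprintf("Hen%d", 1:5))
  df2$facility <- facs[(df2$scan %% 3) + 1]
  a2 <- affiliation_association(scan_data(df2))
  expect_equal(sum(a2$positive) + sum(a2$negative), 0)

  expect_error(affiliation_association(
    scan_data(tibble::tibble(day = 1, scan = 1, individual = "x"))),
    class = "proxnet_empty_error")
})

test_that("null nearest-neighbor data flag close to the nominal two-sided rate", {
  # exchangeable world: roaming animals, no planted structure; the flagged
  # fraction should sit near the 5% two-sided tail (NN data are dependent,
  # so we check a generous band rather than exact calibration)
  sim <- generate_scans(synthetic_config(n_individuals = 15, days = 2,
                                         scans_per_day = 60, seed = 202))
  a <- signed_association(build_nn_matrix(nearest_neighbor_pairs(sim$scans)))
  off <- row(a$sr) != col(a$sr)
  frac <- mean((a$positive + a$negative)[off] > 0)
  expect_lt(frac, 0.12)
})
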