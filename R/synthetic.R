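#' Configuration for the synthetic herd simulator
#'
#' Describes a stated world of individuals with fixed home centers in a
#' rectangular arena, observed by multi-day scan sampling. Each scan is a
#' near-independent snapshot: position = home center + isotropic Gaussian
#' noise (scan intervals of ~10 minutes make successive snapshots close to
#' independent, so no random walk is simulated). Affiliated pairs co-locate:
#' with probability `strength` the lower-indexed member is relocated next to
#' its partner (Gaussian offset, sd 1 m). Avoidance pairs are resampled (up
#' to 20 attempts) until at least `min_distance` apart. Facilities are fixed
#' named points; the nearest one is recorded per individual. Individuals are
#' invisible independently with probability `p_invisible` per scan.
#'
#' @param n_individuals Number of individuals (default 20).
#' @param arena Arena width and height in meters (default 50 x 50, a small
#'   pasture or large enclosure).
#' @param days Number of observation days (default 5).
#' @param scans_per_day Scans per day (default 100).
#' @param home_centers `"random"` (uniform in the arena) or a 2-column
#'   matrix of per-individual centers.
#' @param home_sd Roaming scale in meters around the home center, a scalar
#'   or one value per individual. Small values give territorial individuals
#'   whose fixed geometry itself creates (real) positional associations;
#'   `Inf` (the default) is the fully roaming limit in which positions are
#'   uniform over the arena and nearest-neighbor counts are exchangeable
#'   across dyads in the absence of planted structure. Finite scales use
#'   reflecting arena boundaries.
#' @param affinity_pairs Data frame with columns `i`, `j` (1-based indices,
#'   `i < j`) and `strength` in (0, 1].
#' @param avoidance_pairs Data frame with columns `i`, `j`, `min_distance`
#'   (meters).
#' @param facilities Data frame with columns `name`, `x`, `y`, or `NULL`.
#' @param p_invisible Per-(scan, individual) missingness probability in
#'   [0, 1).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_individuals = 20, arena = c(50, 50),
                             days = 5, scans_per_day = 100,
                             home_centers = "random", home_sd = Inf,
                             affinity_pairs = NULL, avoidance_pairs = NULL,
                             facilities = NULL, p_invisible = 0, seed = 1) {
  stopifnot(n_individuals >= 2, days >= 1, scans_per_day >= 1,
            length(arena) == 2, all(arena > 0), all(home_sd >= 0),
            length(home_sd) %in% c(1L, n_individuals),
            p_invisible >= 0, p_invisible < 1)
  home_sd <- rep(as.numeric(home_sd), length.out = n_individuals)
  if (!is.null(affinity_pairs)) {
    affinity_pairs <- tibble::as_tibble(affinity_pairs)
    stopifnot(all(c("i", "j", "strength") %in% names(affinity_pairs)),
              all(affinity_pairs$strength > 0),
              all(affinity_pairs$strength <= 1),
              all(affinity_pairs$i != affinity_pairs$j))
  }
  if (!is.null(avoidance_pairs)) {
    avoidance_pairs <- tibble::as_tibble(avoidance_pairs)
    stopifnot(all(c("i", "j", "min_distance") %in% names(avoidance_pairs)),
              all(avoidance_pairs$min_distance <
                    sqrt(sum(as.numeric(arena)^2))),
              all(avoidance_pairs$i != avoidance_pairs$j))
  }
  if (!is.null(facilities)) {
    facilities <- tibble::as_tibble(facilities)
    stopifnot(all(c("name", "x", "y") %in% names(facilities)))
  }
  structure(
    list(n_individuals = n_individuals, arena = as.numeric(arena),
         days = days, scans_per_day = scans_per_day,
         home_centers = home_centers, home_sd = home_sd,
         affinity_pairs = affinity_pairs, avoidance_pairs = avoidance_pairs,
         facilities = facilities, p_invisible = p_invisible,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Generate a synthetic scan dataset with known social structure
#'
#' Simulates the world described by a [synthetic_config] and returns both the
#' scan dataset (coordinate mode) and the planted ground truth, so that
#' pipeline recovery can be scored with [recovery_score()].
#'
#' @param cfg A [synthetic_config].
#' @return A list with `scans` (a [scan_data] dataset), `truth` (list with
#'   `affinity`, `avoidance`, `home_centers`), and `avoidance_failures`
#'   (count of scans where an avoidance constraint could not be satisfied in
#'   20 attempts).
#' @export
generate_scans <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)

  n <- cfg$n_individuals
  ids <- sprintf("ID%02d", seq_len(n))
  w <- cfg$arena[1]; h <- cfg$arena[2]
  homes <- if (identical(cfg$home_centers, "random")) {
    cbind(runif(n, 0, w), runif(n, 0, h))
  } else {
    m <- as.matrix(cfg$home_centers)
    stopifnot(nrow(m) == n, ncol(m) == 2)
    m
  }
  fac <- cfg$facilities
  n_scan_total <- cfg$days * cfg$scans_per_day
  failures <- 0L
  out <- vector("list", n_scan_total)
  k <- 0L
  # reflecting boundaries keep territorial animals inside the fence without
  # piling probability mass onto the arena edge
  reflect <- function(v, width) {
    p <- v %% (2 * width)
    ifelse(p > width, 2 * width - p, p)
  }
  draw_position <- function(idx) {
    sd_i <- cfg$home_sd[idx]
    x <- reflect(homes[idx, 1] + rnorm(length(idx), 0, ifelse(is.finite(sd_i), sd_i, 0)), w)
    y <- reflect(homes[idx, 2] + rnorm(length(idx), 0, ifelse(is.finite(sd_i), sd_i, 0)), h)
    roam <- is.infinite(sd_i)
    if (any(roam)) {
      x[roam] <- runif(sum(roam), 0, w)
      y[roam] <- runif(sum(roam), 0, h)
    }
    cbind(x, y)
  }
  for (d in seq_len(cfg$days)) {
    for (s in seq_len(cfg$scans_per_day)) {
      pos <- draw_position(seq_len(n))
      px <- pos[, 1]; py <- pos[, 2]
      if (!is.null(cfg$affinity_pairs)) {
        for (r in seq_len(nrow(cfg$affinity_pairs))) {
          i <- cfg$affinity_pairs$i[r]; j <- cfg$affinity_pairs$j[r]
          lo <- min(i, j); hi <- max(i, j)
          if (runif(1) < cfg$affinity_pairs$strength[r]) {
            px[lo] <- reflect(px[hi] + rnorm(1, 0, 1), w)
            py[lo] <- reflect(py[hi] + rnorm(1, 0, 1), h)
          }
        }
      }
      if (!is.null(cfg$avoidance_pairs)) {
        # resample in sweeps over the whole constraint set so that fixing one
        # pair cannot silently break another pair's distance
        ap <- cfg$avoidance_pairs
        satisfied <- FALSE
        for (attempt in seq_len(20)) {
          viol <- which(sqrt((px[ap$i] - px[ap$j])^2 +
                               (py[ap$i] - py[ap$j])^2) < ap$min_distance)
          if (length(viol) == 0) {
            satisfied <- TRUE
            break
          }
          for (r in viol) {
            pj <- draw_position(ap$j[r])
            px[ap$j[r]] <- pj[, 1]; py[ap$j[r]] <- pj[, 2]
          }
        }
        if (!satisfied) failures <- failures + 1L
      }
      visible <- runif(n) >= cfg$p_invisible
      facility <- rep(NA_character_, n)
      if (!is.null(fac)) {
        dist_to_fac <- outer(px, fac$x, `-`)^2 + outer(py, fac$y, `-`)^2
        facility <- fac$name[apply(dist_to_fac, 1, which.min)]
      }
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        day = d, scan = s, individual = ids,
        x = ifelse(visible, px, NA_real_),
        y = ifelse(visible, py, NA_real_),
        facility = ifelse(visible, facility, NA_character_),
        visible = visible)
    }
  }
  records <- dplyr::bind_rows(out)
  scans <- scan_data(records, individuals = ids,
                     facilities = if (!is.null(fac)) fac$name else NULL,
                     mode = "coordinate",
                     meta = list(generator = "proxnet synthetic",
                                 seed = cfg$seed))
  truth <- list(
    affinity = if (!is.null(cfg$affinity_pairs)) {
      tibble::tibble(a = ids[pmin(cfg$affinity_pairs$i, cfg$affinity_pairs$j)],
                     b = ids[pmax(cfg$affinity_pairs$i, cfg$affinity_pairs$j)],
                     strength = cfg$affinity_pairs$strength)
    } else {
      tibble::tibble(a = character(), b = character(), strength = numeric())
    },
    avoidance = if (!is.null(cfg$avoidance_pairs)) {
      tibble::tibble(a = ids[pmin(cfg$avoidance_pairs$i, cfg$avoidance_pairs$j)],
                     b = ids[pmax(cfg$avoidance_pairs$i, cfg$avoidance_pairs$j)],
                     min_distance = cfg$avoidance_pairs$min_distance)
    } else {
      tibble::tibble(a = character(), b = character(),
                     min_distance = numeric())
    },
    home_centers = tibble::tibble(individual = ids, x = homes[, 1],
                                  y = homes[, 2],
                                  territorial = is.finite(cfg$home_sd)))
  list(scans = scans, truth = truth, avoidance_failures = failures)
}

#' Convert a coordinate-mode dataset to a neighbor-mode dataset
#'
#' Emulates direct nearest-neighbor recording (video-scan style): each
#' visible individual's computed nearest neighbor is written into the
#' `neighbor` column and the coordinates are dropped.
#'
#' @param ds A coordinate-mode [scan_data] dataset.
#' @return A neighbor-mode [scan_data] dataset.
#' @export
as_neighbor_mode <- function(ds) {
  pairs <- nearest_neighbor_pairs(ds)
  records <- dplyr::left_join(
    tibble::as_tibble(ds),
    dplyr::select(tibble::as_tibble(pairs), "day", "scan",
                  individual = "focal", nn = "neighbor"),
    by = c("day", "scan", "individual"))
  records$neighbor <- records$nn
  records$x <- NA_real_
  records$y <- NA_real_
  records$nn <- NULL
  scan_data(records, individuals = individuals(ds),
            facilities = facilities(ds), mode = "neighbor",
            meta = attr(ds, "meta"))
}

#' Score recovery of planted social structure
#'
#' Compares the dyads flagged significant in a [signed_association] against
#' the generator's ground truth: planted affinity pairs vs the positive
#' network's edges, and planted avoidance pairs vs the negative network's
#' edges. When no dyads are flagged at all, precision is undefined; it is
#' reported as 1 with `precision_defined = FALSE`.
#'
#' @param truth The `truth` element returned by [generate_scans()].
#' @param assoc A [signed_association] over the same individuals.
#' @return A tibble with one row per sign: `sign`, `n_planted`, `n_inferred`,
#'   `n_correct`, `precision`, `recall`, `precision_defined`.
#' @export
recovery_score <- function(truth, assoc) {
  dyads_of <- function(g) {
    el <- igraph::as_edgelist(g$graph)
    if (nrow(el) == 0) return(character())
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
  }
  score <- function(planted_tbl, sign) {
    planted <- paste(planted_tbl$a, planted_tbl$b, sep = "|")
    inferred <- dyads_of(build_graph(assoc, sign))
    hits <- length(intersect(planted, inferred))
    tibble::tibble(
      sign = sign,
      n_planted = length(planted),
      n_inferred = length(inferred),
      n_correct = hits,
      precision = if (length(inferred) > 0) hits / length(inferred) else 1,
      recall = if (length(planted) > 0) hits / length(planted) else NA_real_,
      precision_defined = length(inferred) > 0)
  }
  dplyr::bind_rows(score(truth$affinity, "positive"),
                   score(truth$avoidance, "negative"))
}
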