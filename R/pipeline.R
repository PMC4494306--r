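#' Write a labeled matrix as CSV
#'
#' Rows are focal individuals, columns neighbors (or facilities); the first
#' column holds the row identifiers.
#'
#' @param m A matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- tibble::as_tibble(as.data.frame(unclass_matrix(m)), .name_repair = "minimal")
  names(df) <- colnames(m)
  df <- dplyr::bind_cols(tibble::tibble(id = rownames(m)), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a labeled matrix written by [write_matrix_csv()]
#'
#' @param path CSV path.
#' @return A numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}

#' Run the full nearest-neighbor network pipeline
#'
#' Executes every stage end to end and writes the artifact bundle to
#' `out_dir`: the NN count matrix, expected counts and standardized
#' residuals, the positive/negative weight matrices, both sociograms
#' (GraphML) with node-metric tables, NND summary statistics (coordinate
#' mode only), the day-to-day stability series, a one-row comparison table,
#' and a JSON run log echoing package version, seed and parameters. Given
#' the same input, configuration and seed the bundle is byte-identical
#' across runs.
#'
#' @param input A [scan_data] dataset or a path to a CSV readable by
#'   [read_scans()].
#' @param out_dir Output directory (created if needed).
#' @param label Group label used in the comparison row.
#' @param schema Column schema when `input` is a path.
#' @param max_nnd,strict NND filter for coordinate-mode data.
#' @param threshold Significance cut on |SR|.
#' @param method Expected-count null, `"margins"` or `"ipf"`.
#' @param permutations Mantel permutations for the stability series.
#' @param seed Integer seed driving all randomness in the run.
#' @param daylight Optional list with `start_hour`, `end_hour` and
#'   optionally `scan_hours`/`session_start_hour`/`scan_interval_minutes`,
#'   applied via [filter_daylight()].
#' @return Invisibly, a list with the computed objects (`scans`, `pairs`,
#'   `nn_matrix`, `association`, `graphs`, `stability`, `comparison`) and
#'   `files`, the named vector of written paths.
#' @export
run_pipeline <- function(input, out_dir, label = "group",
                         schema = scan_schema(), max_nnd = Inf,
                         strict = FALSE, threshold = 1.96,
                         method = "margins", permutations = 1000,
                         seed = 1, daylight = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  out_file <- function(name) {
    p <- file.path(out_dir, name)
    files[[name]] <<- p
    p
  }

  ds <- if (inherits(input, "scan_data")) {
    input
  } else {
    read_scans(input, schema = schema)
  }
  if (!is.null(daylight)) {
    ds <- filter_daylight(
      ds, daylight$start_hour, daylight$end_hour,
      scan_hours = daylight$scan_hours,
      session_start_hour = daylight$session_start_hour %||% 0,
      scan_interval_minutes = daylight$scan_interval_minutes %||% 60)
  }

  coordinate <- scan_mode(ds) == "coordinate"
  pairs <- tryCatch({
    if (coordinate) {
      filter_by_nnd(nearest_neighbor_pairs(ds), max_nnd, strict = strict)
    } else {
      from_observed_neighbors(ds)
    }
  }, error = function(e) {
    abort(paste0("stage neighbors: ", conditionMessage(e)),
          class = "proxnet_stage_error")
  })

  if (coordinate && any(!is.na(pairs$nnd))) {
    readr::write_csv(nnd_statistics(pairs), out_file("nnd_statistics.csv"),
                     progress = FALSE)
  }

  m <- build_nn_matrix(pairs, individuals = individuals(ds))
  write_matrix_csv(m, out_file("nn_matrix.csv"))

  assoc <- tryCatch(
    signed_association(m, threshold = threshold, method = method),
    error = function(e) {
      abort(paste0("stage association: ", conditionMessage(e)),
            class = "proxnet_stage_error")
    })
  write_matrix_csv(assoc$sr, out_file("sr.csv"))
  write_matrix_csv(assoc$positive, out_file("positive.csv"))
  write_matrix_csv(assoc$negative, out_file("negative.csv"))

  graphs <- list(positive = build_graph(assoc, "positive"),
                 negative = build_graph(assoc, "negative"))
  for (sign in names(graphs)) {
    export_graph(graphs[[sign]], out_file(paste0(sign, ".graphml")),
                 format = "graphml")
    readr::write_csv(node_table(graphs[[sign]]),
                     out_file(paste0("node_metrics_", sign, ".csv")),
                     progress = FALSE)
  }

  stability <- NULL
  if (length(unique(ds$day)) >= 2) {
    stability <- tryCatch(
      daily_series(ds, max_nnd = max_nnd, strict = strict,
                   permutations = permutations, seed = seed),
      error = function(e) {
        warn(paste0("stability series skipped: ", conditionMessage(e)))
        NULL
      })
    if (!is.null(stability)) {
      readr::write_csv(tidy(stability), out_file("stability.csv"),
                       progress = FALSE)
    }
  }

  comparison <- compare_networks(setNames(
    list(list(association = assoc, stability = stability)), label))
  render_report(comparison, out_file("comparison.csv"))
  files[["comparison.txt"]] <- file.path(out_dir, "comparison.txt")

  log <- list(
    package = "proxnet",
    version = as.character(utils::packageVersion("proxnet")),
    label = label,
    seed = seed,
    parameters = list(max_nnd = max_nnd, strict = strict,
                      threshold = threshold, method = method,
                      permutations = permutations,
                      mode = scan_mode(ds)),
    counts = list(records = nrow(ds), individuals = length(individuals(ds)),
                  days = length(unique(ds$day)), pairs = nrow(pairs)))
  jsonlite::write_json(log, out_file("run_log.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(scans = ds, pairs = pairs, nn_matrix = m,
                 association = assoc, graphs = graphs,
                 stability = stability, comparison = comparison,
                 files = files))
}
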