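#' Cross-network comparison table
#'
#' Summarizes several analyzed groups side by side: positive and negative
#' network densities, their sum, the positive share of the total
#' (`100 * positive / (positive + negative)`), and the stability summary
#' (mean consecutive day-to-day Mantel r). All derived columns are computed
#' from unrounded densities; round only when rendering.
#'
#' @param entries A named list; each element is a list with components
#'   `association` (a [signed_association]) and optionally `stability`
#'   (a `stability_series`).
#' @return A tibble with columns `label`, `positive_density`,
#'   `negative_density`, `total_density`, `pct_positive`, `stability`.
#' @export
compare_networks <- function(entries) {
  if (length(entries) == 0) {
    abort("need at least one entry", class = "proxnet_empty_error")
  }
  labels <- names(entries) %||% as.character(seq_along(entries))
  rows <- purrr::map2(entries, labels, function(entry, label) {
    assoc <- entry$association
    pos <- net_density(build_graph(assoc, "positive"))
    neg <- net_density(build_graph(assoc, "negative"))
    stab <- if (!is.null(entry$stability)) {
      entry$stability$mean_consecutive_r
    } else {
      NA_real_
    }
    tibble::tibble(
      label = label,
      positive_density = pos,
      negative_density = neg,
      total_density = pos + neg,
      pct_positive = if (pos + neg > 0) 100 * pos / (pos + neg) else NA_real_,
      stability = stab)
  })
  dplyr::bind_rows(rows)
}

#' Render a comparison table to disk
#'
#' Writes the comparison rows as a CSV and as an aligned plain-text table,
#' both rounded to two decimals (the numbers in memory stay unrounded).
#'
#' @param rows A tibble from [compare_networks()] (may be empty).
#' @param path Output CSV path; the text rendering goes to `path` with a
#'   `.txt` extension.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(rows, path) {
  rounded <- dplyr::mutate(rows,
                           dplyr::across(dplyr::where(is.numeric),
                                         ~ round(.x, 2)))
  readr::write_csv(rounded, path, progress = FALSE)
  txt_path <- sub("\\.csv$", "", path)
  txt_path <- paste0(txt_path, ".txt")
  df <- as.data.frame(rounded)
  lines <- utils::capture.output(print(df, row.names = FALSE))
  writeLines(lines, txt_path)
  invisible(c(csv = path, txt = txt_path))
}
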