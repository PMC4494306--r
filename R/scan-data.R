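#' Column-role schema for scan-sample files
#'
#' Maps the roles the pipeline needs (day, scan, individual, and optionally
#' x, y, neighbor, facility, behavior, visible) onto the column names used in
#' a particular delimited file. Field data come from many ad-hoc recording
#' sheets, so no canonical header is assumed.
#'
#' @param day,scan,individual Required columns: ordinal day index, ordinal
#'   scan index within day, and the individual's identifier.
#' @param x,y Optional planar coordinates in meters.
#' @param neighbor Optional directly observed nearest neighbor identifier.
#' @param facility Optional nearest facility/commodity name.
#' @param behavior Optional behavior label.
#' @param visible Optional logical column; individuals noted as not seen.
#' @return A named list of column names with class `"scan_schema"`.
#' @export
#' @examples
#' scan_schema(individual = "animal_id", x = "pos_x", y = "pos_y")
scan_schema <- function(day = "day", scan = "scan", individual = "individual",
                        x = "x", y = "y", neighbor = "neighbor",
                        facility = "facility", behavior = "behavior",
                        visible = "visible") {
  structure(
    list(day = day, scan = scan, individual = individual, x = x, y = y,
         neighbor = neighbor, facility = facility, behavior = behavior,
         visible = visible),
    class = "scan_schema"
  )
}

scan_columns <- c("day", "scan", "individual", "x", "y", "neighbor",
                  "facility", "behavior", "visible")

#' Construct a validated scan dataset
#'
#' A scan dataset is a tibble with one row per (day, scan, individual)
#' sighting plus metadata attributes: the ordered individual and facility
#' lists, the observation mode, and free-form provenance. Mode is
#' `"coordinate"` when any record carries x-y coordinates (nearest neighbors
#' must then be computed geometrically) and `"neighbor"` when nearest
#' neighbors were recorded directly, as in video scans of hens.
#'
#' @param records A data frame with columns `day`, `scan`, `individual` and
#'   optionally `x`, `y`, `neighbor`, `facility`, `behavior`, `visible`.
#' @param individuals Ordered identifier list; defaults to order of first
#'   appearance in `records`.
#' @param facilities Ordered facility names; defaults to order of first
#'   appearance.
#' @param mode `"coordinate"` or `"neighbor"`; inferred when `NULL`.
#' @param meta Named list of provenance information.
#' @return A tibble of class `"scan_data"`.
#' @export
scan_data <- function(records, individuals = NULL, facilities = NULL,
                      mode = NULL, meta = list()) {
  records <- tibble::as_tibble(records)
  required <- c("day", "scan", "individual")
  missing_req <- setdiff(required, names(records))
  if (length(missing_req) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_req, collapse = ", ")),
          class = "proxnet_schema_error")
  }
  for (col in setdiff(scan_columns, names(records))) {
    records[[col]] <- if (col == "visible") {
      rep(TRUE, nrow(records))
    } else if (col %in% c("x", "y")) {
      rep(NA_real_, nrow(records))
    } else {
      rep(NA_character_, nrow(records))
    }
  }
  records <- tibble::as_tibble(lapply(records[scan_columns], unname))
  records$day <- as.integer(records$day)
  records$scan <- as.integer(records$scan)
  records$individual <- as.character(records$individual)
  records$x <- as.numeric(records$x)
  records$y <- as.numeric(records$y)
  records$neighbor <- as.character(records$neighbor)
  records$facility <- as.character(records$facility)
  records$behavior <- as.character(records$behavior)
  records$visible <- as.logical(records$visible)
  records$visible[is.na(records$visible)] <- TRUE

  validate_scan_records(records)

  if (is.null(individuals)) {
    individuals <- unique(records$individual)
  } else {
    individuals <- as.character(individuals)
    extra <- setdiff(records$individual, individuals)
    if (length(extra) > 0) {
      abort(paste0("individual(s) not in `individuals`: ",
                   paste(extra, collapse = ", ")),
            class = "proxnet_integrity_error")
    }
  }
  if (is.null(facilities)) {
    facilities <- unique(records$facility[!is.na(records$facility)])
  } else {
    facilities <- as.character(facilities)
    extra <- setdiff(records$facility[!is.na(records$facility)], facilities)
    if (length(extra) > 0) {
      abort(paste0("facility(ies) not in `facilities`: ",
                   paste(extra, collapse = ", ")),
            class = "proxnet_integrity_error")
    }
  }
  if (is.null(mode)) {
    mode <- if (any(!is.na(records$x))) "coordinate" else "neighbor"
  }
  mode <- match.arg(mode, c("coordinate", "neighbor"))
  if (mode == "coordinate" && nrow(records) > 0 && !any(!is.na(records$x))) {
    abort("mode is 'coordinate' but no record has coordinates",
          class = "proxnet_integrity_error")
  }

  structure(
    records,
    class = c("scan_data", class(tibble::tibble())),
    individuals = individuals,
    facilities = facilities,
    mode = mode,
    meta = meta
  )
}

validate_scan_records <- function(records) {
  bad_xy <- which(is.na(records$x) != is.na(records$y))
  if (length(bad_xy) > 0) {
    abort(paste0("row ", bad_xy[1],
                 ": x and y must be both present or both absent"),
          class = "proxnet_parse_error")
  }
  self_nn <- which(!is.na(records$neighbor) &
                     records$neighbor == records$individual)
  if (length(self_nn) > 0) {
    abort(paste0("row ", self_nn[1],
                 ": individual recorded as its own nearest neighbor"),
          class = "proxnet_integrity_error")
  }
  unseen_bad <- which(!records$visible &
                        (!is.na(records$x) | !is.na(records$neighbor)))
  if (length(unseen_bad) > 0) {
    abort(paste0("row ", unseen_bad[1],
                 ": not-seen record carries coordinates or a neighbor"),
          class = "proxnet_integrity_error")
  }
  key <- paste(records$day, records$scan, records$individual, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(paste0("duplicate (day, scan, individual) record at row ", dup[1]),
          class = "proxnet_integrity_error")
  }
  invisible(records)
}

#' @export
print.scan_data <- function(x, ...) {
  cat(sprintf(
    "<scan_data> %d records, %d individuals, %d facilities, mode = %s\n",
    nrow(x), length(attr(x, "individuals")), length(attr(x, "facilities")),
    attr(x, "mode")))
  NextMethod()
}

#' Accessors for scan dataset metadata
#'
#' @param ds A `scan_data` object.
#' @return `individuals()` and `facilities()` return character vectors in
#'   their fixed dataset order; `scan_mode()` returns `"coordinate"` or
#'   `"neighbor"`.
#' @export
individuals <- function(ds) attr(ds, "individuals")

#' @rdname individuals
#' @export
facilities <- function(ds) attr(ds, "facilities")

#' @rdname individuals
#' @export
scan_mode <- function(ds) attr(ds, "mode")

#' Read scan-sampled observations from a delimited file
#'
#' Reads a comma-separated file with a header row, maps columns onto the
#' roles in `schema`, validates the records and returns a [scan_data]
#' dataset. Individuals marked by the not-seen token (default `"NS"`) in the
#' neighbor column keep their record with the neighbor treated as missing.
#'
#' @param path Path to a CSV file.
#' @param schema A [scan_schema] mapping roles to column names.
#' @param not_seen Token(s) in the neighbor column meaning "not seen".
#' @return A [scan_data] tibble.
#' @export
read_scans <- function(path, schema = scan_schema(), not_seen = "NS") {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("day", "scan", "individual")
  for (role in required) {
    if (!schema[[role]] %in% names(raw)) {
      abort(paste0("schema error: required column '", schema[[role]],
                   "' (role ", role, ") not found in ", path),
            class = "proxnet_schema_error")
    }
  }
  records <- tibble::tibble(.rows = nrow(raw))
  for (role in scan_columns) {
    col <- schema[[role]]
    if (!is.null(col) && col %in% names(raw)) {
      records[[role]] <- raw[[col]]
    }
  }
  for (role in c("x", "y")) {
    if (role %in% names(records)) {
      txt <- records[[role]]
      num <- suppressWarnings(as.numeric(txt))
      bad <- which(!is.na(txt) & txt != "" & is.na(num))
      if (length(bad) > 0) {
        abort(paste0("row ", bad[1], ": non-numeric ", role,
                     " coordinate '", txt[bad[1]], "'"),
              class = "proxnet_parse_error")
      }
      num[!is.na(txt) & txt == ""] <- NA_real_
      records[[role]] <- num
    }
  }
  if ("neighbor" %in% names(records)) {
    records$neighbor[records$neighbor %in% not_seen] <- NA_character_
  }
  if ("visible" %in% names(records)) {
    records$visible <- as.logical(records$visible)
  }
  scan_data(records, meta = list(source = path))
}

#' Write a scan dataset to CSV
#'
#' Writes canonical column names so that `read_scans()` on the result
#' round-trips to an identical dataset.
#'
#' @param ds A [scan_data] dataset.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scans <- function(ds, path) {
  out <- tibble::as_tibble(ds)[scan_columns]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Map scan indices to clock hours
#'
#' Scans are taken at a fixed interval from a session start hour; this builds
#' the scan-index to hour-of-day lookup used by [filter_daylight()].
#'
#' @param n_scans Number of scans per day.
#' @param session_start_hour Clock hour of the first scan (default 6).
#' @param scan_interval_minutes Minutes between scans (default 10).
#' @return An integer vector of length `n_scans`: hour of day per scan index.
#' @export
scan_hour_map <- function(n_scans, session_start_hour = 6,
                          scan_interval_minutes = 10) {
  minutes <- (seq_len(n_scans) - 1) * scan_interval_minutes
  (session_start_hour + minutes %/% 60) %% 24
}

#' Restrict a scan dataset to a daylight window
#'
#' Keeps only the scans whose clock hour falls in `[start_hour, end_hour)`,
#' e.g. excluding a 21:00-06:00 dark period with `start_hour = 6`,
#' `end_hour = 21`. The individual list is unchanged, so downstream matrices
#' keep their dimensions.
#'
#' @param ds A [scan_data] dataset.
#' @param start_hour,end_hour Half-open hour window to retain.
#' @param scan_hours Optional integer vector mapping scan index to hour of
#'   day; must cover every scan index present. Defaults to
#'   [scan_hour_map()] with the given session parameters.
#' @param session_start_hour,scan_interval_minutes Used to build the default
#'   mapping.
#' @return A filtered [scan_data] dataset.
#' @export
filter_daylight <- function(ds, start_hour, end_hour, scan_hours = NULL,
                            session_start_hour = 0,
                            scan_interval_minutes = 60) {
  scans_present <- sort(unique(ds$scan))
  if (is.null(scan_hours)) {
    scan_hours <- scan_hour_map(max(scans_present, 0),
                                session_start_hour, scan_interval_minutes)
  }
  if (length(scans_present) > 0 && max(scans_present) > length(scan_hours)) {
    abort(paste0("scan_hours does not cover scan index ",
                 max(scans_present)),
          class = "proxnet_schema_error")
  }
  hour <- scan_hours[ds$scan]
  keep <- hour >= start_hour & hour < end_hour
  out <- ds[keep, , drop = FALSE]
  if (nrow(out) == 0 && nrow(ds) > 0) {
    warn("filter_daylight: no scans fall inside the daylight window")
  }
  scan_data(tibble::as_tibble(out), individuals = individuals(ds),
            facilities = facilities(ds), mode = scan_mode(ds),
            meta = attr(ds, "meta"))
}
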