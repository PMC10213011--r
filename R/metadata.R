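#' Default column mapping for the per-image metadata CSV
#'
#' Canonical field names used inside the package, mapped to the header names
#' expected in the CSV. The published table's exact headers are not fixed by
#' the schema description, so the mapping is remappable: pass a modified copy
#' to [read_metadata_table()] if your file uses different headers. Unknown
#' extra columns are always preserved untouched.
#'
#' @return named character vector: canonical name -> CSV header.
#' @export
metadata_columns <- function() {
  c(image_name = "image_name",
    contract_area = "contract_area",
    depth_m = "depth_m",
    latitude = "latitude",
    longitude = "longitude",
    acquired_at = "acquired_at",
    original_scale_cm_per_px = "original_scale_cm_per_px",
    seafloor_class = "seafloor_class",
    class_score = "class_score")
}

SEAFLOOR_CLASSES <- c("A", "B", "C", "D")
CONTRACT_AREAS <- c("German", "Belgian")

parse_utc <- function(x) {
  ts <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  bad <- is.na(ts) & !is.na(x) & nzchar(x)
  if (any(bad))
    ts[bad] <- as.POSIXct(strptime(x[bad], "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  ts
}

# Row-level checks against the schema; returns character vector of problems
# (empty when valid).
validate_metadata_row <- function(row) {
  probs <- character()
  if (is.na(row$acquired_at))
    probs <- c(probs, "acquired_at: unparseable UTC timestamp")
  if (!row$contract_area %in% CONTRACT_AREAS)
    probs <- c(probs, paste0("contract_area: '", row$contract_area,
                             "' not one of {", paste(CONTRACT_AREAS, collapse = ", "), "}"))
  if (is.na(row$depth_m) || row$depth_m < 0)
    probs <- c(probs, "depth_m: must be a nonnegative number")
  if (is.na(row$latitude) || abs(row$latitude) > 90)
    probs <- c(probs, "latitude: must be in [-90, 90]")
  if (is.na(row$longitude) || abs(row$longitude) > 180)
    probs <- c(probs, "longitude: must be in [-180, 180]")
  if (is.na(row$original_scale_cm_per_px) || row$original_scale_cm_per_px <= 0)
    probs <- c(probs, "original_scale_cm_per_px: must be > 0")
  if (!row$seafloor_class %in% SEAFLOOR_CLASSES)
    probs <- c(probs, paste0("seafloor_class: '", row$seafloor_class,
                             "' not one of {", paste(SEAFLOOR_CLASSES, collapse = ", "), "}"))
  if (is.na(row$class_score) || row$class_score < 0 || row$class_score > 1)
    probs <- c(probs, "class_score: must be in [0, 1]")
  probs
}

#' Read and validate the per-image metadata table
#'
#' Reads the CSV accompanying a seafloor image set: one row per image with its
#' name, contract area (German or Belgian), water depth (m), position (decimal
#' degrees), UTC acquisition time (second resolution), original scale
#' (cm/pixel), seafloor substrate class (A-D) and classifier score. Every row
#' is validated against the schema; problems are collected and reported
#' together with their row indices. Records are returned sorted by acquisition
#' time (ties broken by image name), which is the order the light-cone
#' batching relies on.
#'
#' @param path CSV file (UTF-8, comma-separated, header row).
#' @param col_map named character vector mapping canonical field names to the
#'   file's header names; default [metadata_columns()]. Extra columns in the
#'   file are carried through unchanged.
#' @param skip_bad if `TRUE`, rows failing validation are dropped with a
#'   warning; if `FALSE` (default) any invalid row is an error listing every
#'   problem found.
#' @return a `dataset_index`: list with `records` (data.frame sorted by
#'   `acquired_at`, canonical column names) and `col_map`.
#' @seealso [summarize_coverage()], [write_metadata_table()]
#' @export
read_metadata_table <- function(path, col_map = metadata_columns(),
                                skip_bad = FALSE) {
  if (!file.exists(path))
    br_stop(paste0("metadata file not found: ", path), "benthicready_io_error")
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(unname(col_map), names(raw))
  if (length(missing) > 0L)
    br_stop(paste0("metadata CSV is missing required column(s): ",
                   paste(missing, collapse = ", ")),
            "benthicready_schema_error")
  extra <- setdiff(names(raw), unname(col_map))
  if (nrow(raw) == 0L) {
    warning("metadata CSV has a header but no rows; returning an empty index")
    rec <- data.frame(image_name = character(), contract_area = character(),
                      depth_m = numeric(), latitude = numeric(),
                      longitude = numeric(),
                      acquired_at = as.POSIXct(character(), tz = "UTC"),
                      original_scale_cm_per_px = numeric(),
                      seafloor_class = character(), class_score = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(list(records = rec, col_map = col_map),
                     class = "dataset_index"))
  }
  rec <- data.frame(
    image_name = raw[[col_map[["image_name"]]]],
    contract_area = raw[[col_map[["contract_area"]]]],
    depth_m = suppressWarnings(as.numeric(raw[[col_map[["depth_m"]]]])),
    latitude = suppressWarnings(as.numeric(raw[[col_map[["latitude"]]]])),
    longitude = suppressWarnings(as.numeric(raw[[col_map[["longitude"]]]])),
    acquired_at = parse_utc(raw[[col_map[["acquired_at"]]]]),
    original_scale_cm_per_px =
      suppressWarnings(as.numeric(raw[[col_map[["original_scale_cm_per_px"]]]])),
    seafloor_class = raw[[col_map[["seafloor_class"]]]],
    class_score = suppressWarnings(as.numeric(raw[[col_map[["class_score"]]]])),
    stringsAsFactors = FALSE
  )
  for (cn in extra) rec[[cn]] <- raw[[cn]]

  problems <- lapply(seq_len(nrow(rec)), function(i)
    validate_metadata_row(rec[i, , drop = FALSE]))
  bad <- which(lengths(problems) > 0L)
  if (length(bad) > 0L) {
    msgs <- vapply(bad, function(i)
      paste0("row ", i, ": ", paste(problems[[i]], collapse = "; ")),
      character(1))
    if (!skip_bad)
      br_stop(paste0(length(bad), " invalid metadata row(s):\n",
                     paste(msgs, collapse = "\n")),
              "benthicready_schema_error")
    warning(paste0("dropping ", length(bad), " invalid metadata row(s):\n",
                   paste(msgs, collapse = "\n")))
    rec <- rec[-bad, , drop = FALSE]
  }
  ord <- order(rec$acquired_at, rec$image_name)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec, col_map = col_map), class = "dataset_index")
}

#' @export
print.dataset_index <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("<dataset_index> %d image record(s)\n", n))
  if (n > 0L) {
    cat("  time span:",
        format(min(x$records$acquired_at), "%Y-%m-%d %H:%M:%S", tz = "UTC"),
        "to",
        format(max(x$records$acquired_at), "%Y-%m-%d %H:%M:%S", tz = "UTC"),
        "UTC\n")
  }
  invisible(x)
}

#' Write a metadata table back to CSV
#'
#' Canonical columns are renamed through the index's column mapping, so a
#' read/write cycle round-trips the original headers. Timestamps are written
#' as `YYYY-MM-DDTHH:MM:SS` (UTC); numeric fields keep full double precision.
#'
#' @param index a `dataset_index` (or a data.frame with canonical columns).
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata_table <- function(index, path) {
  if (inherits(index, "dataset_index")) {
    rec <- index$records
    col_map <- index$col_map
  } else {
    rec <- index
    col_map <- metadata_columns()
  }
  out <- rec
  out$acquired_at <- format(rec$acquired_at, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  for (num in c("depth_m", "latitude", "longitude",
                "original_scale_cm_per_px", "class_score"))
    out[[num]] <- format(rec[[num]], digits = 15, trim = TRUE,
                         scientific = FALSE)
  canon <- intersect(names(col_map), names(out))
  names(out)[match(canon, names(out))] <- unname(col_map[canon])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize the geographic and temporal coverage of an image set
#'
#' Computes the median position (even-count medians are the mean of the two
#' central values), the bounding box, and the acquisition time span over all
#' records — the coverage summary the metadata schema reports for the
#' archived dataset.
#'
#' @param index a `dataset_index` from [read_metadata_table()], or a
#'   data.frame with `latitude`, `longitude`, `acquired_at` columns.
#' @return list with `median_lat`, `median_lon`, `bounds` (named list with
#'   `south`, `north`, `west`, `east`) and `time_span` (`POSIXct` length 2),
#'   plus the record count `n`.
#' @export
summarize_coverage <- function(index) {
  rec <- if (inherits(index, "dataset_index")) index$records else index
  if (is.null(rec) || nrow(rec) == 0L)
    br_stop("cannot summarize coverage of an empty index",
            "benthicready_schema_error")
  list(
    median_lat = stats::median(rec$latitude),
    median_lon = stats::median(rec$longitude),
    bounds = list(south = min(rec$latitude), north = max(rec$latitude),
                  west = min(rec$longitude), east = max(rec$longitude)),
    time_span = c(min(rec$acquired_at), max(rec$acquired_at)),
    n = nrow(rec)
  )
}
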