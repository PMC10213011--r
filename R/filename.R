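#' Parse a seafloor image file name
#'
#' File names follow `<cruise_station_platform_date_time.JPG>`, e.g.
#' `"SO268_100-1_OFOS_20190304_093510.JPG"`. The name is split on underscores
#' only, so station identifiers may contain hyphens; the last two tokens are
#' always the date (`YYYYMMDD`) and time (`HHMMSS`), the token before them is
#' the platform, the first token the cruise, and everything in between the
#' station. Date and time combine to a UTC timestamp at second resolution.
#'
#' @param name file name with a `.JPG`/`.jpg` extension (PNG is accepted too,
#'   for lossless pipeline intermediates that keep the convention).
#' @return a list with elements `cruise`, `station`, `platform`, `date`
#'   (`Date`), `time` (`"HH:MM:SS"`), `acquisition_time` (`POSIXct`, UTC) and
#'   `extension`. [build_image_filename()] is its exact inverse.
#' @examples
#' parse_image_filename("SO268_100-1_OFOS_20190304_093510.JPG")$station
#' @seealso [build_image_filename()]
#' @export
parse_image_filename <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regmatches(name, regexec("\\.(jpe?g|png)$", name, ignore.case = TRUE))[[1]]
  if (length(m) == 0L)
    br_stop(paste0("'", name, "': missing .JPG/.jpg extension"),
            "benthicready_parse_error")
  ext <- m[1]
  stem <- sub("\\.(jpe?g|png)$", "", name, ignore.case = TRUE)
  tok <- strsplit(stem, "_", fixed = TRUE)[[1]]
  n <- length(tok)
  if (n < 5L)
    br_stop(paste0("'", name, "': expected >= 5 underscore-separated tokens ",
                   "(cruise_station_platform_date_time), got ", n),
            "benthicready_parse_error")
  date_tok <- tok[n - 1L]
  time_tok <- tok[n]
  if (!grepl("^[0-9]{8}$", date_tok))
    br_stop(paste0("'", name, "': date token '", date_tok,
                   "' is not YYYYMMDD"), "benthicready_parse_error")
  if (!grepl("^[0-9]{6}$", time_tok))
    br_stop(paste0("'", name, "': time token '", time_tok,
                   "' is not HHMMSS"), "benthicready_parse_error")
  ts <- as.POSIXct(strptime(paste0(date_tok, time_tok), "%Y%m%d%H%M%S",
                            tz = "UTC"))
  if (is.na(ts) ||
      format(ts, "%Y%m%d%H%M%S", tz = "UTC") != paste0(date_tok, time_tok))
    br_stop(paste0("'", name, "': date/time tokens '", date_tok, "_", time_tok,
                   "' are not a valid UTC timestamp"),
            "benthicready_parse_error")
  list(
    cruise = tok[1L],
    station = paste(tok[2:(n - 3L)], collapse = "_"),
    platform = tok[n - 2L],
    date = as.Date(ts),
    time = format(ts, "%H:%M:%S", tz = "UTC"),
    acquisition_time = ts,
    extension = ext
  )
}

#' Assemble a file name from parsed fields
#'
#' Inverse of [parse_image_filename()]: on any well-formed name,
#' `build_image_filename(parse_image_filename(x))` returns `x` exactly.
#'
#' @param fields a list as returned by [parse_image_filename()], or the
#'   individual components.
#' @param cruise,station,platform character tokens (ignored when `fields`
#'   is given).
#' @param acquisition_time `POSIXct` (UTC).
#' @param extension file extension including the dot (default `".JPG"`).
#' @return the assembled file name.
#' @export
build_image_filename <- function(fields = NULL, cruise, station, platform,
                                 acquisition_time, extension = ".JPG") {
  if (!is.null(fields)) {
    cruise <- fields$cruise; station <- fields$station
    platform <- fields$platform
    acquisition_time <- fields$acquisition_time
    extension <- fields$extension %||% extension
  }
  paste0(paste(cruise, station, platform,
               format(acquisition_time, "%Y%m%d", tz = "UTC"),
               format(acquisition_time, "%H%M%S", tz = "UTC"), sep = "_"),
         extension)
}
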