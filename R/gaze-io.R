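#' @include AllClasses.R AllGenerics.R
NULL

.logCols <- c("subject_id", "image_id", "day", .gazeCols)

#' Read eye-tracker logs from CSV
#'
#' The on-disk format is comma-separated UTF-8 with header
#' `subject_id,image_id,day,timestamp,left_x,left_y,right_x,right_y,left_pupil,right_pupil`;
#' an empty cell is a missing value. `readGazeLog()` expects a file covering
#' a single (subject, image) presentation; `readGazeLogs()` splits a file
#' into one [GazeLog-class] per presentation, in order of first appearance.
#'
#' Malformed numeric cells are reported with their data-row number, and
#' timestamps that are not non-decreasing within a presentation are
#' rejected.
#'
#' @param path path to a CSV file.
#' @return `readGazeLog()`: a [GazeLog-class]. `readGazeLogs()`: a list of
#'   them.
#' @seealso [writeGazeLog()]
#' @export
readGazeLog <- function(path) {
  logs <- readGazeLogs(path)
  if (length(logs) != 1L)
    stop(sprintf("file %s holds %d (subject, image) presentations; expected one (use readGazeLogs)",
                 path, length(logs)))
  logs[[1L]]
}

#' @rdname readGazeLog
#' @export
readGazeLogs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = "")
  missing <- setdiff(.logCols, names(raw))
  if (length(missing))
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  num <- raw
  for (cc in c("day", .gazeCols)) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(!is.na(raw[[cc]]) & is.na(v))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at data row %d of %s",
                   cc, bad[1L], path))
    num[[cc]] <- v
  }
  if (nrow(num) == 0L)
    return(list(GazeLog("", "", num[, .gazeCols, drop = FALSE])))
  key <- paste(num$subject_id, num$image_id, sep = "\r")
  lapply(unique(key), function(k) {
    rows <- num[key == k, , drop = FALSE]
    if (is.unsorted(rows$timestamp))
      stop(sprintf("timestamps not sorted for subject %s, image %s in %s",
                   rows$subject_id[1L], rows$image_id[1L], path))
    GazeLog(rows$subject_id[1L], rows$image_id[1L],
            rows[, .gazeCols, drop = FALSE],
            day = if (is.na(rows$day[1L])) 1L else rows$day[1L])
  })
}

#' Write eye-tracker logs to CSV
#'
#' Inverse of [readGazeLog()]: writing then re-reading reproduces the log
#' exactly (missing values round-trip as empty cells).
#'
#' @param log a [GazeLog-class] or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGazeLog <- function(log, path) {
  if (is(log, "GazeLog")) log <- list(log)
  rows <- do.call(rbind, lapply(log, function(l) {
    r <- gazeRecords(l)
    if (nrow(r) == 0L) {
      df <- as.data.frame(setNames(rep(list(numeric(0)), length(.logCols)), .logCols))
      df$subject_id <- character(0); df$image_id <- character(0)
      return(df)
    }
    cbind(data.frame(subject_id = subjectId(l), image_id = imageId(l),
                     day = sessionDay(l)), r)
  }))
  write.csv(rows[, .logCols, drop = FALSE], path, row.names = FALSE, na = "",
            quote = FALSE)
  invisible(path)
}

.mergeRecords <- function(r) {
  lxy <- !is.na(r$left_x) & !is.na(r$left_y)
  rxy <- !is.na(r$right_x) & !is.na(r$right_y)
  x <- ifelse(lxy & rxy, (r$left_x + r$right_x) / 2,
              ifelse(lxy, r$left_x, ifelse(rxy, r$right_x, NA_real_)))
  y <- ifelse(lxy & rxy, (r$left_y + r$right_y) / 2,
              ifelse(lxy, r$left_y, ifelse(rxy, r$right_y, NA_real_)))
  lp <- !is.na(r$left_pupil); rp <- !is.na(r$right_pupil)
  p <- ifelse(lp & rp, (r$left_pupil + r$right_pupil) / 2,
              ifelse(lp, r$left_pupil, ifelse(rp, r$right_pupil, NA_real_)))
  data.frame(timestamp = r$timestamp, x = x, y = y, pupil = p)
}

#' @rdname mergeBinocular
setMethod("mergeBinocular", "GazeLog", function(x) .mergeRecords(gazeRecords(x)))

#' @rdname mergeBinocular
setMethod("mergeBinocular", "data.frame", function(x) .mergeRecords(x))
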