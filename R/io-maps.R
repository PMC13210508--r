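#' @include AllClasses.R AllGenerics.R saliency.R
NULL

#' Read and write saliency maps as plain text
#'
#' Dense whitespace-separated numeric arrays (one grid row per line),
#' lossless to full double precision with `digits = 17`.
#'
#' @param map a [SaliencyMap-class].
#' @param path file path.
#' @param kind map kind used when reading.
#' @return `writeSaliencyMap()`: `path` invisibly; `readSaliencyMap()`: a
#'   [SaliencyMap-class].
#' @export
writeSaliencyMap <- function(map, path) {
  v <- mapValues(map)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#", mapKind(map)),
               apply(v, 1, function(r) paste(formatC(r, digits = 17, format = "g"),
                                             collapse = " "))), con)
  invisible(path)
}

#' @rdname writeSaliencyMap
#' @export
readSaliencyMap <- function(path, kind = NULL) {
  lines <- readLines(path)
  if (is.null(kind)) {
    kind <- if (startsWith(lines[1], "# ")) sub("^# ", "", lines[1]) else "PSM"
  }
  lines <- lines[!startsWith(lines, "#")]
  vals <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  SaliencyMap(do.call(rbind, vals), kind)
}

#' Read and write fixation grids as sparse CSV
#'
#' Sparse `x,y,count` rows (0-based cells), plus a header comment carrying
#' the grid size and drop tallies so the round trip is exact.
#'
#' @param grid a [CountGrid-class].
#' @param path file path.
#' @return `writeCountGrid()`: `path` invisibly; `readCountGrid()`: a
#'   [CountGrid-class].
#' @export
writeCountGrid <- function(grid, path) {
  ct <- gridCounts(grid)
  nz <- which(ct > 0, arr.ind = TRUE)
  df <- data.frame(x = nz[, 2] - 1L, y = nz[, 1] - 1L, count = ct[nz])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# width=%d height=%d missing=%d oob=%d", ncol(ct), nrow(ct),
                     grid@nMissing, grid@nOutOfBounds), con)
  write.csv(df[order(df$y, df$x), ], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCountGrid
#' @export
readCountGrid <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- as.integer(regmatches(hdr, gregexpr("[0-9]+", hdr))[[1]])
  df <- read.csv(path, comment.char = "#")
  ct <- matrix(0L, meta[2], meta[1])
  if (nrow(df)) ct[cbind(df$y + 1L, df$x + 1L)] <- as.integer(df$count)
  new("CountGrid", counts = ct, nMissing = meta[3], nOutOfBounds = meta[4])
}
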