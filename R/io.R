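# Plain-text movie I/O. Height stacks are stored as whitespace-separated
# numeric frame blocks with a JSON sidecar carrying the calibration
# (pixel size, frame interval) and any ground-truth annotations, so
# movies written by the generator round-trip losslessly through files.

#' Write a topography movie to a plain-text stack + JSON sidecar
#'
#' Writes `<stem>.txt` (frames as blank-line-separated blocks of
#' whitespace-separated heights in nm, row per scan line) and
#' `<stem>.json` (pixel size, frame interval, dimensions, timestamps and
#' optional extra metadata such as ground truth).
#'
#' @param movie a [topography_movie()].
#' @param stem output path without extension.
#' @param extra optional list of additional sidecar entries (must be
#'   JSON-serializable).
#' @return The stem, invisibly.
#' @export
write_movie <- function(movie, stem, extra = NULL) {
  stopifnot(inherits(movie, "topography_movie"))
  txt <- paste0(stem, ".txt")
  con <- file(txt, "w")
  on.exit(close(con))
  for (f in seq_along(movie$frames)) {
    utils::write.table(format(movie$frames[[f]], digits = 8, trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    writeLines("", con)
  }
  meta <- list(pixel_size = movie$pixel_size,
               frame_interval = movie$frame_interval,
               timestamps = movie$timestamps,
               n_frames = length(movie$frames),
               dim = dim(movie$frames[[1]]))
  if (!is.null(extra)) meta$extra <- extra
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Read a topography movie written by [write_movie()]
#'
#' @param stem path without extension (expects `<stem>.txt` and
#'   `<stem>.json`).
#' @return A list: `movie` (a [topography_movie()]) and `extra` (sidecar
#'   metadata, or NULL).
#' @export
read_movie <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  lines <- readLines(paste0(stem, ".txt"))
  blocks <- split(lines, cumsum(lines == "")[seq_along(lines)])
  frames <- list()
  for (b in blocks) {
    b <- b[b != ""]
    if (length(b) == 0) next
    m <- do.call(rbind, lapply(strsplit(trimws(b), "\\s+"), as.numeric))
    frames[[length(frames) + 1]] <- m
  }
  if (length(frames) != meta$n_frames)
    stop("frame count mismatch between stack and sidecar")
  mv <- topography_movie(frames, meta$pixel_size, meta$frame_interval,
                         timestamps = meta$timestamps)
  list(movie = mv, extra = meta$extra)
}

#' Read rough particle seed coordinates
#'
#' CSV with columns `frame`, `x`, `y` (nm) and optionally `species`; the
#' hand-picked seed format for [refine_particle()].
#'
#' @param path CSV file path.
#' @return Data frame of seeds.
#' @export
read_particle_seeds <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "x", "y")
  if (!all(need %in% names(df)))
    stop("seed CSV must have columns frame, x, y")
  df
}
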