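#' Landmark track container
#'
#' Per-frame 2D coordinates plus confidence for named body parts, with the
#' frame rate. Neither the pose CSV nor the image formats carry a rate, so
#' `fps` is supplied by the caller (default 500, the filming rate the
#' pipeline assumes).
#'
#' @param landmarks named list of data.frames with columns `x`, `y`,
#'   `confidence`, all of equal length.
#' @param fps frames per second (> 0).
#' @return object of class `point_track`.
#' @export
point_track <- function(landmarks, fps = 500) {
  stopifnot(is.list(landmarks), length(landmarks) >= 1, fps > 0)
  ns <- vapply(landmarks, nrow, integer(1))
  if (length(unique(ns)) != 1)
    stop("all landmark series must have equal length", call. = FALSE)
  for (nm in names(landmarks)) {
    lm <- landmarks[[nm]]
    if (!all(c("x", "y", "confidence") %in% names(lm)))
      stop("landmark '", nm, "' lacks x/y/confidence columns", call. = FALSE)
    if (any(lm$confidence < 0 | lm$confidence > 1, na.rm = TRUE))
      stop("confidence must lie in [0, 1]", call. = FALSE)
  }
  structure(list(landmarks = landmarks, fps = fps), class = "point_track")
}

#' @export
print.point_track <- function(x, ...) {
  cat(sprintf("<point_track> %d frames @ %g fps; landmarks: %s\n",
              nrow(x$landmarks[[1]]), x$fps,
              paste(names(x$landmarks), collapse = ", ")))
  invisible(x)
}

#' Binary frame stack container
#'
#' @param frames list of logical matrices of identical shape
#'   (TRUE = foreground).
#' @param fps frames per second.
#' @param px_per_BL optional pixels-per-body-length scale.
#' @return object of class `binary_stack`.
#' @export
binary_stack <- function(frames, fps = 500, px_per_BL = NULL) {
  stopifnot(length(frames) >= 1, fps > 0)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same shape", call. = FALSE)
  structure(list(frames = lapply(frames, function(f) {
    storage.mode(f) <- "logical"; f
  }), fps = fps, px_per_BL = px_per_BL), class = "binary_stack")
}

#' @export
print.binary_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<binary_stack> %d frames of %d x %d px @ %g fps\n",
              length(x$frames), d[1], d[2], x$fps))
  invisible(x)
}

#' Read a pose-estimation CSV (three-row header dialect)
#'
#' Parses the CSV dialect written by markerless pose-estimation tools:
#' three header rows labelled `scorer`, `bodyparts` and `coords`, then one
#' row per frame with per-landmark `x`, `y` and (optionally) `likelihood`
#' columns. A missing likelihood column defaults confidence to 1. Points
#' with confidence below `min_confidence` have their coordinates set to
#' `NA` for interpolation downstream.
#'
#' @param path file path.
#' @param fps frame rate to attach (not stored in the format; default 500).
#' @param min_confidence mask threshold in `[0, 1]`; default 0 keeps all.
#' @return a [point_track].
#' @export
read_pose_csv <- function(path, fps = 500, min_confidence = 0) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) < 4)
    stop("pose CSV truncated: need 3 header rows plus data", call. = FALSE)
  labels <- tolower(trimws(raw[1:3, 1]))
  expected <- c("scorer", "bodyparts", "coords")
  bad <- which(labels != expected)
  if (length(bad))
    stop(sprintf("malformed pose CSV header: row %d should start with '%s', found '%s'",
                 bad[1], expected[bad[1]], raw[bad[1], 1]), call. = FALSE)
  parts <- trimws(as.character(raw[2, -1]))
  coords <- tolower(trimws(as.character(raw[3, -1])))
  body <- raw[-(1:3), -1, drop = FALSE]
  bm <- as.matrix(body)
  num <- suppressWarnings(matrix(as.numeric(bm), nrow = nrow(bm)))
  bad <- which(is.na(num) & !(trimws(bm) %in% c("", "NA", "NaN")),
               arr.ind = TRUE)
  if (length(bad))
    stop(sprintf("non-numeric cell at data row %d, column %d ('%s')",
                 bad[1, 1], bad[1, 2] + 1, bm[bad[1, 1], bad[1, 2]]),
         call. = FALSE)
  lms <- list()
  for (pt in unique(parts)) {
    sel <- which(parts == pt)
    cc <- coords[sel]
    need <- c("x", "y") %in% cc
    if (!all(need))
      stop("bodypart '", pt, "' lacks x/y columns", call. = FALSE)
    conf <- if ("likelihood" %in% cc)
      num[, sel[match("likelihood", cc)]] else rep(1, nrow(num))
    lm <- data.frame(x = num[, sel[match("x", cc)]],
                     y = num[, sel[match("y", cc)]],
                     confidence = conf)
    if (min_confidence > 0) {
      mask <- !is.na(lm$confidence) & lm$confidence < min_confidence
      lm$x[mask] <- NA_real_
      lm$y[mask] <- NA_real_
    }
    lms[[pt]] <- lm
  }
  point_track(lms, fps = fps)
}

#' Write a point track in the pose-estimation CSV dialect
#'
#' @param track a [point_track].
#' @param path output file path.
#' @param scorer scorer label written in the first header row.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(track, path, scorer = "swimkin") {
  stopifnot(inherits(track, "point_track"))
  nms <- names(track$landmarks)
  nf <- nrow(track$landmarks[[1]])
  header1 <- c("scorer", rep(scorer, 3 * length(nms)))
  header2 <- c("bodyparts", rep(nms, each = 3))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), length(nms)))
  dat <- do.call(cbind, lapply(track$landmarks, function(lm)
    cbind(lm$x, lm$y, lm$confidence)))
  dat <- cbind(seq_len(nf) - 1L, format(dat, digits = 15, trim = TRUE,
                                        scientific = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header1, collapse = ","),
               paste(header2, collapse = ","),
               paste(header3, collapse = ",")), con)
  utils::write.table(dat, con, sep = ",", col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binary frame stack from a TIFF or a PNG directory
#'
#' Accepts a multi-page TIFF file or a directory of PNG files
#' (lexicographic order). Any nonzero pixel is foreground.
#'
#' @param path TIFF file or directory of PNGs.
#' @param fps frame rate to attach (default 500).
#' @return a [binary_stack].
#' @export
read_frames <- function(path, fps = 500) {
  to_logical <- function(img) {
    if (length(dim(img)) == 3) img <- img[, , 1]
    img > 0
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG files in directory: ", path,
                             call. = FALSE)
    frames <- lapply(files, function(f) to_logical(png::readPNG(f)))
  } else {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, to_logical)
  }
  binary_stack(frames, fps = fps)
}

#' Write a binary frame stack
#'
#' Writes a multi-page TIFF when `path` ends in `.tif`/`.tiff`, otherwise
#' a directory of zero-padded PNG files.
#'
#' @param stack a [binary_stack].
#' @param path output TIFF path or directory.
#' @return `path`, invisibly.
#' @export
write_frames <- function(stack, path) {
  stopifnot(inherits(stack, "binary_stack"))
  imgs <- lapply(stack$frames, function(f) {
    storage.mode(f) <- "double"; f
  })
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(imgs, path, bits.per.sample = 8)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (k in seq_along(imgs))
      png::writePNG(imgs[[k]],
                    file.path(path, sprintf("frame_%05d.png", k)))
  }
  invisible(path)
}

#' Read or write a run configuration file
#'
#' Structured YAML whose keys mirror the [swimmer_params()] and
#' [study_design()] fields.
#'
#' @param path file path.
#' @return for `read_config`, a named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config named list to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
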