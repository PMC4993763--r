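#' Frame sequences
#'
#' A `frame_sequence` holds an ordered list of 2-D grayscale intensity
#' matrices (all with identical dimensions, values in \[0, 1\]) together with
#' the frame rate in Hz. It is the canonical in-memory representation of a
#' fixed-camera recording of a seated dyad.
#'
#' @param frames list of numeric matrices, all with identical dimensions.
#' @param fps frames per second (Hz).
#' @param source_id free-text provenance string.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps, source_id = "") {
  if (!is.list(frames) || length(frames) < 2L) {
    stop_format("a frame sequence needs at least 2 frames")
  }
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    stop_format("all frames must be numeric matrices")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_format("frames have mismatched dimensions")
  }
  check_fps(fps)
  structure(
    list(frames = frames, fps = fps, source_id = as.character(source_id)),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<frame_sequence> %d frames, %d x %d px, %.3g fps (%.1f s)%s\n",
    length(x$frames), d[1], d[2], x$fps, length(x$frames) / x$fps,
    if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""
  ))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

# Rec. 601 luma weights; colour carries no extra information for motion energy
luma_weights <- c(0.299, 0.587, 0.114)

to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc >= 3L) {
      return(img[, , 1] * luma_weights[1] + img[, , 2] * luma_weights[2] +
               img[, , 3] * luma_weights[3])
    }
    return(img[, , 1])
  }
  stop_format("unsupported image array shape")
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_format(sprintf("unsupported image format '.%s' (PNG/TIFF supported)", ext))
  )
  to_gray(img)
}

#' Read a recording into a frame sequence
#'
#' Reads a directory of sequential image frames (PNG or TIFF; files are
#' sorted lexicographically into temporal order) and converts each frame to
#' grayscale with standard luma weighting. Image-sequence directories carry
#' no frame-rate metadata, so `fps` must be supplied. Video container files
#' are not decodable here; export the recording as an image sequence or a
#' precomputed energy CSV (see [read_energy_csv()]).
#'
#' @param path directory containing the image frames.
#' @param fps frames per second (Hz); required for image sequences.
#' @param source_id provenance label, defaults to the path.
#' @return A [frame_sequence()].
#' @export
read_frames <- function(path, fps = NULL, source_id = NULL) {
  if (!file.exists(path)) stop_input(sprintf("input path '%s' does not exist", path))
  if (!dir.exists(path)) {
    stop_format(
      "video container decoding is not supported; supply a directory of PNG/TIFF frames or an energy CSV"
    )
  }
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  files <- files[order(basename(files))]
  if (length(files) < 2L) stop_input(sprintf("'%s' contains fewer than 2 readable frames", path))
  if (is.null(fps)) {
    stop_config("image sequences carry no fps metadata; supply `fps`")
  }
  frames <- lapply(files, read_one_image)
  fs <- frame_sequence(frames, fps, source_id %||% path)
  message(sprintf("read %d frames at %g fps from %s", length(frames), fps, path))
  fs
}

#' Write a frame sequence as an image sequence
#'
#' @param fs a [frame_sequence()].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(fs, dir, prefix = "frame") {
  stopifnot(inherits(fs, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(fs$frames)
  paths <- file.path(dir, sprintf("%s_%05d.png", prefix, seq_len(n)))
  for (i in seq_len(n)) {
    img <- pmin(pmax(fs$frames[[i]], 0), 1)
    png::writePNG(img, paths[i])
  }
  invisible(paths)
}

#' Define the two-person region split
#'
#' The frame is divided by a vertical boundary (the middle of the desk in a
#' face-to-face seating arrangement) into a subject region and an actor
#' region. Columns are 0-based with half-open intervals: `subject_side =
#' "left"` assigns columns `[0, boundary_col)` to the subject and
#' `[boundary_col, frame_width)` to the actor. The two regions always
#' partition the frame.
#'
#' @param frame_width frame width in pixels.
#' @param boundary_col 0-based column index of the vertical split; defaults
#'   to the frame midline `floor(frame_width / 2)`.
#' @param subject_side which side of the boundary the subject occupies.
#' @return An object of class `region_split`.
#' @export
split_regions <- function(frame_width, boundary_col = NULL,
                          subject_side = c("left", "right")) {
  subject_side <- match.arg(subject_side)
  if (!is_scalar_number(frame_width) || frame_width < 2) {
    stop_domain("`frame_width` must be at least 2 pixels")
  }
  boundary_col <- boundary_col %||% floor(frame_width / 2)
  if (!is_scalar_number(boundary_col) || boundary_col <= 0 || boundary_col >= frame_width) {
    stop_domain(sprintf(
      "`boundary_col` must lie strictly inside the frame (0 < col < %d)", frame_width
    ))
  }
  structure(
    list(frame_width = as.integer(frame_width),
         boundary_col = as.integer(boundary_col),
         subject_side = subject_side),
    class = "region_split"
  )
}

#' @export
print.region_split <- function(x, ...) {
  cat(sprintf("<region_split> width %d, boundary at col %d, subject on the %s\n",
              x$frame_width, x$boundary_col, x$subject_side))
  invisible(x)
}

# 1-based column indices for each person (internal)
subject_cols <- function(split) {
  if (split$subject_side == "left") seq_len(split$boundary_col)
  else (split$boundary_col + 1L):split$frame_width
}
actor_cols <- function(split) {
  setdiff(seq_len(split$frame_width), subject_cols(split))
}

#' Region masks for a frame geometry
#'
#' @param split a [split_regions()] object.
#' @param frame_height frame height in pixels.
#' @return A list of two logical matrices, `subject` and `actor`, that
#'   partition the frame (every pixel belongs to exactly one mask).
#' @export
region_masks <- function(split, frame_height) {
  stopifnot(inherits(split, "region_split"))
  m <- matrix(FALSE, frame_height, split$frame_width)
  subj <- m
  subj[, subject_cols(split)] <- TRUE
  list(subject = subj, actor = !subj)
}
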