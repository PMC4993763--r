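#' Paired kinetic-energy series
#'
#' A `dyad_energy` tibble holds the per-frame total kinetic energy (sum of
#' squared pixel velocities, px^2/frame^2) of the subject and the actor.
#' Element `n` is the energy of the motion between frames `n` and `n + 1`,
#' so a recording of `N` frames yields `N - 1` energy samples.
#'
#' @param subject,actor non-negative numeric vectors of equal length.
#' @param fps frame rate of the source recording (Hz).
#' @param start_frame 0-based index of the first frame pair.
#' @return A tibble of class `dyad_energy` with columns `frame`, `time`,
#'   `subject`, `actor` and an `fps` attribute.
#' @export
dyad_energy <- function(subject, actor, fps, start_frame = 0L) {
  if (length(subject) != length(actor)) {
    stop_format("subject and actor energy series must have equal length")
  }
  if (length(subject) < 1L) stop_format("empty energy series")
  if (anyNA(subject) || anyNA(actor)) stop_validation("energy series contain missing values")
  if (any(subject < 0) || any(actor < 0)) {
    stop_validation("kinetic energies must be non-negative")
  }
  check_fps(fps)
  frame <- start_frame + seq_along(subject) - 1L
  out <- tibble(frame = as.integer(frame), time = frame / fps,
                subject = as.numeric(subject), actor = as.numeric(actor))
  attr(out, "fps") <- fps
  class(out) <- c("dyad_energy", class(out))
  out
}

energy_fps <- function(de, fps = NULL) {
  fps <- fps %||% attr(de, "fps")
  if (is.null(fps)) stop_config("no fps available; supply `fps`")
  check_fps(fps)
}

#' Write a dyad energy series to CSV
#'
#' Writes columns `frame_index, subject_energy, actor_energy` with the frame
#' rate recorded both as a `# fps:` comment header and in a JSON sidecar
#' (`<path>.json`), which also stores any extra metadata passed via `meta`.
#'
#' @param de a [dyad_energy()] tibble.
#' @param path output CSV path.
#' @param meta named list of extra metadata for the sidecar.
#' @return Invisibly, `path`.
#' @export
write_energy_csv <- function(de, path, meta = list()) {
  stopifnot(inherits(de, "dyad_energy"))
  fps <- energy_fps(de)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps: %.10g", fps), con)
  utils::write.csv(
    data.frame(frame_index = de$frame, subject_energy = de$subject,
               actor_energy = de$actor),
    con, row.names = FALSE
  )
  sidecar <- c(list(fps = fps, n = nrow(de)), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dyad energy series from CSV
#'
#' Accepts the CSV layout written by [write_energy_csv()]: columns
#' `frame_index, subject_energy, actor_energy`, frame rate in a `# fps:`
#' comment line or a `<path>.json` sidecar. An explicit `fps` argument
#' overrides both.
#'
#' @param path CSV path.
#' @param fps optional frame-rate override (Hz).
#' @return A [dyad_energy()] tibble.
#' @export
read_energy_csv <- function(path, fps = NULL) {
  if (!file.exists(path)) stop_input(sprintf("input path '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE)
  if (is.null(fps)) {
    m <- regmatches(hdr, regexec("fps:\\s*([0-9.eE+-]+)", hdr))
    m <- m[vapply(m, length, integer(1)) == 2L]
    if (length(m)) {
      fps <- as.numeric(m[[1]][2])
    } else if (file.exists(paste0(path, ".json"))) {
      fps <- jsonlite::read_json(paste0(path, ".json"))$fps
    }
    if (is.null(fps)) stop_config("no fps found in header or sidecar; supply `fps`")
  }
  nf <- utils::count.fields(textConnection(lines[body]), sep = ",")
  if (length(unique(nf)) != 1L) stop_format("ragged CSV: rows have differing column counts")
  df <- utils::read.csv(textConnection(lines[body]))
  need <- c("frame_index", "subject_energy", "actor_energy")
  if (!all(need %in% names(df))) {
    stop_format(sprintf("energy CSV must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyNA(df[need])) stop_format("energy CSV contains missing values")
  if (any(df$subject_energy < 0) || any(df$actor_energy < 0)) {
    stop_validation("energy CSV contains negative energies")
  }
  dyad_energy(df$subject_energy, df$actor_energy, fps = fps,
              start_frame = df$frame_index[1])
}

#' Trim an energy series to an analysis interval
#'
#' Recordings are analysed from the moment both interlocutors are seated to
#' the end of the conversational phase; the cut points are supplied in
#' seconds relative to the start of the series.
#'
#' @param de a [dyad_energy()] tibble.
#' @param start,end analysis interval in seconds (`NULL` = no trimming).
#' @return A trimmed [dyad_energy()] tibble.
#' @export
trim_energy <- function(de, start = NULL, end = NULL) {
  stopifnot(inherits(de, "dyad_energy"))
  fps <- energy_fps(de)
  t0 <- de$time - de$time[1]
  keep <- rep(TRUE, nrow(de))
  if (!is.null(start)) keep <- keep & t0 >= start
  if (!is.null(end)) keep <- keep & t0 < end
  if (!any(keep)) stop_domain("trim interval leaves no samples")
  dyad_energy(de$subject[keep], de$actor[keep], fps, start_frame = de$frame[keep][1])
}
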