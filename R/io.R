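#' Default column-name mapping for recording files
#'
#' Maps the on-disk header names (Bonsai-style) to the canonical frame fields.
#' Acquisition setups differ in header naming, so every reader accepts a map.
#'
#' @return Named character vector: canonical name -> on-disk header.
#' @export
default_col_map <- function() {
  c(frame_index = "FrameCounter", timestamp = "Timestamp",
    led_state = "LedState", roi_intensity = "Region0")
}

#' Read a frame-level photometry recording
#'
#' Reads a recording where each row is one camera frame with its frame
#' counter, timestamp, LED state and mean ROI pixel intensity. CSV is the
#' canonical dialect; XLSX is accepted because Bonsai-based rigs log one.
#' Frame order on disk is preserved; monotonicity problems are surfaced by
#' [validate_stream()], never silently repaired.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, or `"xlsx"`.
#' @param col_map Named character vector mapping canonical fields
#'   (`frame_index`, `timestamp`, `led_state`, `roi_intensity`) to the file's
#'   header names; see [default_col_map()].
#' @return Tibble of frames with the canonical columns.
#' @export
read_recording <- function(path, format = c("auto", "csv", "xlsx"),
                           col_map = default_col_map()) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("recording file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.xlsx$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  stopifnot(all(c("frame_index", "timestamp", "led_state", "roi_intensity")
                %in% names(col_map)))
  raw <- if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package", call. = FALSE)
    }
    readxl::read_xlsx(path, col_types = "numeric")
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(raw) == 0) {
    stop("empty recording file: ", path, call. = FALSE)
  }
  missing <- setdiff(unname(col_map), names(raw))
  if (length(missing)) {
    stop("recording is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    frame_index = as_numeric_col(raw[[col_map[["frame_index"]]]], "frame_index"),
    timestamp = as_numeric_col(raw[[col_map[["timestamp"]]]], "timestamp"),
    led_state = as_numeric_col(raw[[col_map[["led_state"]]]], "led_state"),
    roi_intensity = as_numeric_col(raw[[col_map[["roi_intensity"]]]],
                                   "roi_intensity")
  )
  if (!all(out$led_state %in% c(0, 1))) {
    stop("led_state must be 0/1; offending rows: ",
         paste(utils::head(which(!out$led_state %in% c(0, 1)), 5),
               collapse = ", "), call. = FALSE)
  }
  out$frame_index <- as.integer(out$frame_index)
  out$led_state <- as.integer(out$led_state)
  out
}

as_numeric_col <- function(x, name) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop("non-numeric or non-finite ", name, " at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  v
}

#' Write a frame-level recording
#'
#' Inverse of [read_recording()] on the canonical column set; used by the
#' simulator and for round-trip testing.
#'
#' @param frames Tibble of frames (canonical columns).
#' @param path Output path.
#' @param format `"csv"` or `"xlsx"`.
#' @param col_map As in [read_recording()]; written as the file header.
#' @return `path`, invisibly.
#' @export
write_recording <- function(frames, path, format = c("csv", "xlsx"),
                            col_map = default_col_map()) {
  format <- match.arg(format)
  canon <- c("frame_index", "timestamp", "led_state", "roi_intensity")
  stopifnot(all(canon %in% names(frames)))
  out <- frames[canon]
  names(out) <- unname(col_map[canon])
  if (format == "csv") {
    # full-precision text so write -> read is the exact identity
    out[] <- lapply(out, function(x) {
      if (is.double(x)) sprintf("%.17g", x) else x
    })
    readr::write_csv(out, path, progress = FALSE)
  } else {
    write_minimal_xlsx(out, path)
  }
  invisible(path)
}

#' Quality-control report for a frame stream
#'
#' Report-only: computes duration, per-LED-state frame counts, dropped-frame
#' gaps (jumps in the frame counter), and a duty-cycle estimate, and flags
#' streams that cannot support interleaved-control analysis. Callers decide
#' on exclusion; nothing is repaired.
#'
#' @param frames Tibble of frames.
#' @param schedule A [session_schedule()] giving the expected durations.
#' @param min_frames_per_state Minimum LED-on and LED-off frames for a pass;
#'   the default is far below the ~1230 expected from a 60 s interleaved
#'   window at 41 fps, so only grossly truncated streams fail.
#' @return One-row tibble: counts, duration, `n_gaps`, `dropped_frames`,
#'   `duty_cycle`, `pass`, `reason`.
#' @export
validate_stream <- function(frames, schedule = session_schedule(),
                            min_frames_per_state = 100) {
  stopifnot(is.data.frame(frames))
  n_on <- sum(frames$led_state == 1)
  n_off <- sum(frames$led_state == 0)
  jumps <- diff(frames$frame_index)
  gaps <- jumps[jumps > 1]
  non_monotone <- sum(jumps <= 0)
  duration <- if (nrow(frames)) diff(range(frames$timestamp)) else 0
  reason <- character()
  if (n_on == 0) reason <- c(reason, "no excitation frames")
  if (n_off == 0) reason <- c(reason, "no control frames")
  if (n_on > 0 && n_on < min_frames_per_state) {
    reason <- c(reason, "too few excitation frames")
  }
  if (n_off > 0 && n_off < min_frames_per_state) {
    reason <- c(reason, "too few control frames")
  }
  if (non_monotone > 0) reason <- c(reason, "frame counter not increasing")
  tibble::new_tibble(
    list(
      n_frames = nrow(frames), n_on = n_on, n_off = n_off,
      duration_s = duration,
      n_gaps = length(gaps), dropped_frames = sum(gaps - 1L),
      non_monotone = non_monotone,
      duty_cycle = if (n_on + n_off > 0) n_on / (n_on + n_off) else NA_real_,
      pass = length(reason) == 0,
      reason = if (length(reason)) paste(reason, collapse = "; ") else NA_character_
    ),
    nrow = 1L
  )
}

#' Write an experiment manifest
#'
#' @param manifest Tibble with columns `file`, `animal_id`, `genotype`,
#'   `treatment`, `dose`, `route`, `hour` (extra columns are carried along).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load and validate an experiment manifest
#'
#' Reads a JSON manifest (an array of session records), checks that every
#' referenced recording file exists, that each (animal, treatment) block has
#' its pre-treatment hour-0 session, and that no (animal, treatment, hour)
#' is duplicated.
#'
#' @param path Path to `manifest.json`.
#' @param check_files Verify that recording files exist next to the manifest.
#' @return Tibble of session metadata with a `file` column of absolute paths.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(raw) && !is.data.frame(raw) && !is.null(raw$sessions)) {
    raw <- raw$sessions
  }
  m <- tibble::as_tibble(raw)
  required <- c("file", "animal_id", "treatment", "hour")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    stop("manifest missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- m |>
    dplyr::count(.data$animal_id, .data$treatment, .data$hour) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate (animal, treatment, hour) in manifest: ",
         paste(sprintf("%s/%s/h%s", dup$animal_id, dup$treatment, dup$hour),
               collapse = ", "), call. = FALSE)
  }
  no_baseline <- m |>
    dplyr::group_by(.data$animal_id, .data$treatment) |>
    dplyr::summarise(has0 = any(.data$hour == 0), .groups = "drop") |>
    dplyr::filter(!.data$has0)
  if (nrow(no_baseline)) {
    stop("manifest block(s) missing the pre-treatment hour-0 session: ",
         paste(sprintf("(%s, %s)", no_baseline$animal_id,
                       no_baseline$treatment), collapse = ", "),
         call. = FALSE)
  }
  m$file <- file.path(dirname(normalizePath(path)), m$file)
  if (check_files) {
    absent <- m$file[!file.exists(m$file)]
    if (length(absent)) {
      stop("manifest references absent recording file(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  m
}
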