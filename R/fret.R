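#' Session FRET by interleaved-control subtraction
#'
#' The session FRET statistic is the mean ROI intensity of LED-on frames
#' minus the mean ROI intensity of the interleaved LED-off (control) frames
#' within the analysis window. Subtracting the interleaved control removes
#' ambient light and common-mode motion artifacts that affect both LED
#' states alike.
#'
#' @param frames Tibble of frames (canonical columns, see
#'   [read_recording()]).
#' @param window Analysis window `c(start_s, end_s)` in session time;
#'   frames with `start <= timestamp < end` are used. Defaults to the whole
#'   stream. In the standard protocol the window is the interleaved minute,
#'   excluding the no-LED lead-in.
#' @return One-row tibble: `fret` (camera counts), `n_on`, `n_off`,
#'   `window_start`, `window_end`.
#' @export
#' @examples
#' fr <- tibble::tibble(frame_index = 0:3, timestamp = 0:3 / 41,
#'                      led_state = c(0L, 1L, 0L, 1L),
#'                      roi_intensity = c(10, 50, 10, 50))
#' compute_fret(fr)$fret # 40
compute_fret <- function(frames, window = NULL) {
  stopifnot(is.data.frame(frames))
  ts <- frames$timestamp
  if (is.null(window)) window <- c(min(ts), max(ts) + 1)
  stopifnot(length(window) == 2, window[1] < window[2])
  in_win <- ts >= window[1] & ts < window[2]
  led <- frames$led_state[in_win]
  intensity <- frames$roi_intensity[in_win]
  n_on <- sum(led == 1L)
  n_off <- sum(led == 0L)
  if (n_on == 0 || n_off == 0) {
    stop("analysis window lacks frames of one LED state (n_on = ", n_on,
         ", n_off = ", n_off, "): cannot form the interleaved control",
         call. = FALSE)
  }
  tibble::new_tibble(
    list(
      fret = mean(intensity[led == 1L]) - mean(intensity[led == 0L]),
      n_on = n_on, n_off = n_off,
      window_start = window[1], window_end = window[2]
    ),
    nrow = 1L
  )
}

#' Delta-FRET time course relative to the pre-treatment baseline
#'
#' Expresses each session's FRET as percent change from the same day's
#' pre-treatment (hour-0) FRET:
#' `delta_fret = 100 * (FRET - pre-treatment FRET) / pre-treatment FRET`.
#' The hour-0 entry is exactly 0 by construction.
#'
#' @param fret_by_hour Tibble with columns `hour` and `fret`, one row per
#'   session of a recording day; must contain `hour == 0`.
#' @return The input with a `delta_fret` (%) column, sorted by hour.
#' @export
#' @examples
#' compute_delta_fret(tibble::tibble(hour = 0:1, fret = c(100, 110)))
compute_delta_fret <- function(fret_by_hour) {
  stopifnot(is.data.frame(fret_by_hour),
            all(c("hour", "fret") %in% names(fret_by_hour)))
  if (!any(fret_by_hour$hour == 0)) {
    stop("pre-treatment (hour-0) session missing: delta-FRET has no baseline",
         call. = FALSE)
  }
  f0 <- fret_by_hour$fret[fret_by_hour$hour == 0]
  if (length(f0) != 1) {
    stop("exactly one hour-0 session required per recording day", call. = FALSE)
  }
  if (!is.finite(f0) || f0 <= 0) {
    stop("pre-treatment FRET must be positive (got ", format(f0),
         "): baseline failed, delta-FRET undefined", call. = FALSE)
  }
  out <- dplyr::arrange(fret_by_hour, .data$hour)
  out$delta_fret <- 100 * (out$fret - f0) / f0
  out$delta_fret[out$hour == 0] <- 0
  out
}

#' Trapezoidal area under a delta-FRET time course
#'
#' Sums `(y_A + y_B) / 2 * (t_B - t_A)` over consecutive timepoint pairs;
#' non-uniform spacing is supported. Units are %*h when `hours` is in hours
#' and `delta_fret` in percent.
#'
#' @param hours Strictly increasing timepoints (h); at least 2.
#' @param delta_fret Delta-FRET values (%) at those timepoints.
#' @return The area (%*h).
#' @export
#' @examples
#' auc_trapezoid(0:3, c(0, 10, 10, 10)) # 25
auc_trapezoid <- function(hours, delta_fret) {
  stopifnot(is.numeric(hours), is.numeric(delta_fret),
            length(hours) == length(delta_fret))
  if (length(hours) < 2) {
    stop("at least two timepoints are needed for a trapezoidal area",
         call. = FALSE)
  }
  if (is.unsorted(hours, strictly = TRUE)) {
    stop("hours must be strictly increasing", call. = FALSE)
  }
  if (anyNA(delta_fret)) {
    stop("delta_fret contains missing values", call. = FALSE)
  }
  sum((utils::head(delta_fret, -1) + utils::tail(delta_fret, -1)) / 2 *
        diff(hours))
}

#' Summarise one recording day
#'
#' Maximum delta-FRET (the highest value observed during the recording day,
#' including the hour-0 zero), minimum delta-FRET (relevant for
#' calpain-activating treatments, which push FRET below baseline), and the
#' trapezoidal AUC over the day. The AUC requires the complete hour grid:
#' computing it across a gap would silently change the quantity, so it is
#' reported `NA` when any scheduled hour is missing, while max/min use the
#' hours available.
#'
#' @param series Tibble with `hour` and `delta_fret` columns (one recording
#'   day, hour 0 included).
#' @param full_hours The complete hour grid the AUC is defined over.
#' @return One-row tibble: `max_delta_fret`, `min_delta_fret`, `auc`.
#' @export
#' @examples
#' summarize_day(tibble::tibble(hour = 0:3, delta_fret = c(0, 50, 0, -25)))
summarize_day <- function(series, full_hours = c(0, 1, 2, 3)) {
  stopifnot(is.data.frame(series),
            all(c("hour", "delta_fret") %in% names(series)))
  series <- dplyr::arrange(series, .data$hour)
  auc <- if (all(full_hours %in% series$hour)) {
    keep <- series$hour %in% full_hours
    auc_trapezoid(series$hour[keep], series$delta_fret[keep])
  } else {
    NA_real_
  }
  tibble::tibble(
    max_delta_fret = max(series$delta_fret),
    min_delta_fret = min(series$delta_fret),
    auc = auc
  )
}

#' Process a whole photometry experiment
#'
#' Runs the full analysis for every (animal, treatment) recording day: QC via
#' [validate_stream()], session FRET over the interleaved window via
#' [compute_fret()], the delta-FRET time course via [compute_delta_fret()],
#' and the day summary via [summarize_day()]. Failing blocks are reported,
#' not fatal: one broken recording day never aborts the rest of the
#' experiment.
#'
#' @param x A `photofret_cohort` (in-memory simulation), a path to a
#'   `manifest.json`, or a manifest tibble whose `file` column points at
#'   recording files.
#' @param schedule A [session_schedule()]; defines the analysis window (the
#'   interleaved minute) and the full hour grid for the AUC. Taken from the
#'   cohort object when available.
#' @param min_frames_per_state QC threshold passed to [validate_stream()].
#' @return An object of class `photofret_experiment`: list with `delta_fret`
#'   (long tibble: animal, genotype, treatment, dose, route, hour, fret,
#'   delta_fret), `summaries` (one row per animal x treatment), `qc`
#'   (per-session QC reports), and `failures` (blocks that errored, with
#'   messages).
#' @export
process_experiment <- function(x, schedule = NULL, min_frames_per_state = 100) {
  if (inherits(x, "photofret_cohort")) {
    manifest <- x$manifest
    if (is.null(schedule)) schedule <- x$schedule
    get_frames <- if (is.null(x$sessions)) {
      function(row) read_recording(file.path(x$dir, row$file))
    } else {
      function(row) x$sessions[[row$session]]
    }
  } else {
    manifest <- if (is.character(x)) load_manifest(x) else tibble::as_tibble(x)
    get_frames <- function(row) read_recording(row$file)
  }
  if (is.null(schedule)) schedule <- session_schedule()
  window <- c(schedule$off_lead_s, schedule$off_lead_s + schedule$interleaved_s)

  for (col in c("genotype", "dose", "route")) {
    if (!col %in% names(manifest)) manifest[[col]] <- NA
  }
  blocks <- split(manifest, ~ animal_id + treatment, drop = TRUE)

  qc_list <- list(); series_list <- list(); summary_list <- list()
  failures <- list()
  for (b in blocks) {
    b <- dplyr::arrange(b, .data$hour)
    res <- tryCatch({
      frets <- purrr::map_dbl(seq_len(nrow(b)), function(j) {
        fr <- get_frames(b[j, ])
        qc <- validate_stream(fr, schedule, min_frames_per_state)
        qc$animal_id <- b$animal_id[j]; qc$treatment <- b$treatment[j]
        qc$hour <- b$hour[j]
        qc_list[[length(qc_list) + 1L]] <<- qc
        if (!qc$pass) {
          stop("QC failure at hour ", b$hour[j], ": ", qc$reason,
               call. = FALSE)
        }
        compute_fret(fr, window)$fret
      })
      series <- compute_delta_fret(tibble::tibble(hour = b$hour, fret = frets))
      series <- dplyr::bind_cols(
        b[match(series$hour, b$hour),
          c("animal_id", "genotype", "treatment", "dose", "route")],
        series
      )
      list(series = series,
           summary = dplyr::bind_cols(
             tibble::tibble(animal_id = b$animal_id[1],
                            treatment = b$treatment[1]),
             summarize_day(series, full_hours = schedule$hours)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        animal_id = b$animal_id[1], treatment = b$treatment[1],
        message = conditionMessage(res)
      )
    } else {
      series_list[[length(series_list) + 1L]] <- res$series
      summary_list[[length(summary_list) + 1L]] <- res$summary
    }
  }

  structure(
    list(
      delta_fret = dplyr::bind_rows(series_list),
      summaries = dplyr::bind_rows(summary_list),
      qc = dplyr::bind_rows(qc_list),
      failures = dplyr::bind_rows(failures)
    ),
    class = "photofret_experiment"
  )
}

#' @export
print.photofret_experiment <- function(x, ...) {
  cat("<photofret_experiment> ",
      dplyr::n_distinct(x$delta_fret$animal_id), " animals, ",
      dplyr::n_distinct(x$delta_fret$treatment), " treatments, ",
      nrow(x$delta_fret), " sessions analysed",
      if (nrow(x$failures)) paste0(", ", nrow(x$failures), " block(s) failed"),
      "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an analysed experiment
#'
#' @param x A `photofret_experiment`.
#' @param ... Unused.
#' @return The long delta-FRET tibble (one row per analysed session).
#' @method tidy photofret_experiment
#' @export
tidy.photofret_experiment <- function(x, ...) x$delta_fret

#' One-row overview of an analysed experiment
#'
#' @param x A `photofret_experiment`.
#' @param ... Unused.
#' @return One-row tibble with animal/treatment/session counts and the number
#'   of failed blocks.
#' @method glance photofret_experiment
#' @export
glance.photofret_experiment <- function(x, ...) {
  tibble::tibble(
    n_animals = dplyr::n_distinct(x$delta_fret$animal_id),
    n_treatments = dplyr::n_distinct(x$delta_fret$treatment),
    n_sessions = nrow(x$delta_fret),
    n_failed_blocks = nrow(x$failures)
  )
}

#' Write experiment results to disk
#'
#' Emits the tidy `delta_fret.csv`, the per-day `summaries.csv`, and a JSON
#' run report (QC table and failed blocks).
#'
#' @param experiment A `photofret_experiment`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_results <- function(experiment, dir) {
  stopifnot(inherits(experiment, "photofret_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(experiment$delta_fret, file.path(dir, "delta_fret.csv"),
                   progress = FALSE)
  readr::write_csv(experiment$summaries, file.path(dir, "summaries.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(qc = experiment$qc, failures = experiment$failures),
    file.path(dir, "run_report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
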