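#' Render one photometry recording session as a frame stream
#'
#' Produces the frame-level table a Bonsai-style acquisition would log: a
#' no-excitation lead-in followed by a window of strictly alternating
#' LED-off/LED-on frames (starting LED-off; the LED-state column, not frame
#' parity, is authoritative downstream). LED-on frames carry
#' `gain(t) * S(t) + ambient`, LED-off frames carry `ambient` alone; both get
#' the common-mode artifact and per-frame Gaussian noise added. The optical
#' gain decays as `gain * exp(-bleach_rate * cumulative LED-on seconds)`:
#' photobleaching accrues only while the excitation LED is on, which is why
#' brief interleaved recordings keep it negligible.
#'
#' @param params A [sensor_params()] object.
#' @param sensor Intact sensor during the session: a single number (constant
#'   pool), a numeric vector with one value per frame, or a function of
#'   session time in hours.
#' @param schedule A [session_schedule()]; only the lead-in and window
#'   durations are used here.
#' @param artifact Optional common-mode trace added to every frame regardless
#'   of LED state: a numeric vector per frame or a function of session time in
#'   seconds.
#' @param cum_on_offset_s LED-on seconds already accumulated earlier in the
#'   recording day (bleaching carries across the day's sessions).
#' @param seed Optional seed for the per-frame noise; when `NULL` the current
#'   RNG stream is used.
#' @return Tibble of frames: `frame_index` (from 0), `timestamp` (s),
#'   `led_state` (0/1), `roi_intensity` (camera counts).
#' @export
#' @examples
#' p <- sensor_params(noise_sd = 0)
#' fr <- render_session(p, sensor = steady_state_sensor(p))
#' table(fr$led_state)
render_session <- function(params, sensor, schedule = session_schedule(),
                           artifact = NULL, cum_on_offset_s = 0, seed = NULL) {
  stopifnot(inherits(params, "sensor_params"),
            inherits(schedule, "session_schedule"))
  fps <- params$fps
  n_lead <- round(fps * schedule$off_lead_s)
  n_int <- round(fps * schedule$interleaved_s)
  n <- n_lead + n_int
  ts <- (seq_len(n) - 1) / fps
  led <- c(rep(0L, n_lead), rep_len(c(0L, 1L), n_int))

  s_vals <- if (is.function(sensor)) {
    sensor(ts / 3600)
  } else if (length(sensor) == 1) {
    rep(sensor, n)
  } else {
    stopifnot(length(sensor) == n)
    sensor
  }
  if (any(!is.finite(s_vals)) || any(s_vals < 0)) {
    stop("sensor trace must be finite and non-negative", call. = FALSE)
  }

  art <- if (is.null(artifact)) {
    0
  } else if (is.function(artifact)) {
    artifact(ts)
  } else {
    stopifnot(length(artifact) %in% c(1L, n))
    artifact
  }

  # LED-on exposure completed before each frame drives the bleached gain
  prior_on_s <- cum_on_offset_s + (cumsum(led) - led) / fps
  gain_t <- params$gain * exp(-params$bleach_rate * prior_on_s)

  if (!is.null(seed)) set.seed(seed)
  noise <- if (params$noise_sd > 0) {
    stats::rnorm(n, 0, params$noise_sd)
  } else {
    0
  }
  intensity <- ifelse(led == 1L, gain_t * s_vals, 0) + params$ambient +
    art + noise

  tibble::new_tibble(
    list(
      frame_index = seq_len(n) - 1L,
      timestamp = ts,
      led_state = led,
      roi_intensity = as.numeric(intensity)
    ),
    nrow = n
  )
}

# Cyclic Latin square of treatment order: animal i runs treatment
# ((i + j - 2) mod k) + 1 on day j, so each treatment occupies each day
# position equally often when n_animals is a multiple of k.
latin_square_order <- function(n_animals, n_treatments) {
  rows <- lapply(seq_len(n_animals), function(i) {
    as.integer((i - 1 + seq_len(n_treatments) - 1) %% n_treatments) + 1L
  })
  matrix(unlist(rows), nrow = n_animals, ncol = n_treatments, byrow = TRUE)
}

#' Simulate a photometry cohort
#'
#' Generates a full simulated experiment: per-animal lognormal jitter on
#' sensor synthesis and optical gain, treatment days ordered by a cyclic
#' Latin square (or in listed order), per treatment a pre-dose session at
#' hour 0 followed by sessions at the scheduled hours post-dose, each rendered
#' as a frame stream with photobleaching carried across the day, a slow
#' common-mode motion artifact, and camera noise. The intact-sensor time
#' course is obtained by Runge-Kutta integration of the synthesis/cleavage
#' kinetics under each drug's activity trace; since the kinetics are linear in
#' `k_syn`, one solve per treatment is scaled exactly to each animal.
#'
#' With `out_dir = NULL` the sessions stay in memory; otherwise each session
#' is written as a recording file (CSV by default, XLSX available) plus a
#' JSON manifest, and the run is byte-reproducible under a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @param params A [sensor_params()] object (per-animal `k_syn` and `gain` are
#'   jittered around these values).
#' @param schedule A [session_schedule()].
#' @param out_dir Output directory, or `NULL` to keep sessions in memory.
#' @param overwrite Refuse to clobber existing recording files unless `TRUE`.
#' @param format Recording file format, `"csv"` or `"xlsx"`.
#' @return An object of class `photofret_cohort`: a list with `manifest`
#'   (tibble), `sessions` (named list of frame tibbles; `NULL` entries when
#'   written to disk), `schedule`, `params`, and `spec`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_animals = 2, seed = 42))
#' cohort$manifest
simulate_cohort <- function(spec, params = sensor_params(),
                            schedule = session_schedule(), out_dir = NULL,
                            overwrite = FALSE, format = c("csv", "xlsx")) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(params, "sensor_params"),
            inherits(schedule, "session_schedule"))
  format <- match.arg(format)
  set.seed(spec$seed)

  n <- spec$n_animals
  treatments <- spec$treatments
  k <- length(treatments)
  animal_ids <- sprintf("m%02d", seq_len(n))
  genotypes <- rep_len(spec$genotypes, n)

  # mean-preserving lognormal jitter on synthesis rate and gain
  sd_syn <- sqrt(log(1 + spec$cv_k_syn^2))
  sd_gain <- sqrt(log(1 + spec$cv_gain^2))
  k_syn_i <- params$k_syn * stats::rlnorm(n, -sd_syn^2 / 2, sd_syn)
  gain_i <- params$gain * stats::rlnorm(n, -sd_gain^2 / 2, sd_gain)

  day_order <- if (spec$latin_square) {
    latin_square_order(n, k)
  } else {
    matrix(rep(seq_len(k), each = n), nrow = n)
  }

  session_h <- (schedule$off_lead_s + schedule$interleaved_s) / 3600
  t_max <- max(schedule$hours) + session_h
  t_grid <- seq(0, t_max, by = 1 / 3600)

  # one kinetic solve per treatment at k_syn = 1, scaled per animal
  base_params <- params
  base_params$k_syn <- 1
  u_fun <- lapply(treatments, function(tr) {
    act <- activity_trace(tr, params$a0, t_grid)
    if (tr$kind == "vehicle") {
      u0 <- steady_state_sensor(base_params)
      function(t) rep(u0, length(t))
    } else {
      sol <- sensor_pool_trace(base_params, act, t_grid)
      stats::approxfun(sol$time, sol$sensor, rule = 2)
    }
  })
  u0 <- steady_state_sensor(base_params)

  rows <- list()
  sessions <- list()
  for (i in seq_len(n)) {
    p_i <- params
    p_i$gain <- gain_i[i]
    for (d in seq_len(k)) {
      tr <- treatments[[day_order[i, d]]]
      cum_on <- 0
      for (h in schedule$hours) {
        s_fun <- if (h == 0) {
          function(t) rep(k_syn_i[i] * u0, length(t))
        } else {
          local({
            uf <- u_fun[[tr$label]]
            h0 <- h
            ks <- k_syn_i[i]
            function(t) ks * uf(h0 + t)
          })
        }
        # slow sinusoidal common-mode artifact, random phase per session
        phase <- stats::runif(1, 0, 2 * pi)
        art <- local({
          ph <- phase
          function(t_s) sin(2 * pi * t_s / 17 + ph)
        })
        fr <- render_session(p_i, sensor = s_fun, schedule = schedule,
                             artifact = art, cum_on_offset_s = cum_on)
        cum_on <- cum_on + sum(fr$led_state) / params$fps
        key <- sprintf("%s_%s_h%d", animal_ids[i], sanitize_label(tr$label), h)
        sessions[[key]] <- fr
        rows[[length(rows) + 1L]] <- tibble::new_tibble(
          list(
            session = key,
            file = if (is.null(out_dir)) NA_character_ else
              paste0(key, ".", format),
            animal_id = animal_ids[i], genotype = genotypes[i],
            treatment = tr$label, dose = tr$dose, route = tr$route,
            hour = h, day_index = d
          ),
          nrow = 1L
        )
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)

  if (!is.null(out_dir)) {
    write_cohort(manifest, sessions, out_dir, overwrite, format)
    sessions <- NULL
  }

  structure(
    list(manifest = manifest, sessions = sessions, schedule = schedule,
         params = params, spec = spec,
         dir = if (is.null(out_dir)) NULL else out_dir),
    class = "photofret_cohort"
  )
}

sanitize_label <- function(x) gsub("[^A-Za-z0-9._-]+", "-", x)

write_cohort <- function(manifest, sessions, out_dir, overwrite, format) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, manifest$file)
  exists <- file.exists(paths)
  if (any(exists) && !overwrite) {
    stop("refusing to overwrite existing recording files: ",
         paste(utils::head(paths[exists], 3), collapse = ", "),
         if (sum(exists) > 3) " ..." else "", call. = FALSE)
  }
  for (j in seq_len(nrow(manifest))) {
    write_recording(sessions[[manifest$session[j]]], paths[j], format = format)
  }
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' @export
print.photofret_cohort <- function(x, ...) {
  cat("<photofret_cohort> ", x$spec$n_animals, " animals x ",
      length(x$spec$treatments), " treatments x ",
      length(x$schedule$hours), " hours (seed ", x$spec$seed, ")\n", sep = "")
  if (!is.null(x$dir)) cat("  written to:", x$dir, "\n")
  invisible(x)
}
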