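#' Calpain-activity time course under a drug effect
#'
#' Evaluates `a(t) = a0 * (1 -/+ magnitude * B(t))` on a grid of hours since
#' dosing, where `B(t)` is a Bateman-type onset/washout curve
#' `(exp(-k_off t) - exp(-k_on t))` normalised to unit peak (the `k_on = k_off`
#' limit `t * exp(-k t)` is handled analytically). The minus sign applies to
#' inhibitors, the plus sign to activators; vehicle returns constant basal
#' activity. Times at or before dosing (`t <= 0`) carry no drug effect.
#'
#' @param profile A [drug_profile()].
#' @param a0 Basal calpain activity (>= 0).
#' @param t Hours since dose; non-negative values must be non-decreasing.
#' @return Tibble with columns `time` (h) and `activity` (activity-units).
#' @export
#' @examples
#' activity_trace(drug_profile("inhibitor", magnitude = 0.5), a0 = 1,
#'                t = seq(0, 3, by = 0.5))
activity_trace <- function(profile, a0, t) {
  stopifnot(inherits(profile, "drug_profile"), is.numeric(a0), a0 >= 0,
            is.numeric(t), !is.unsorted(t))
  b <- bateman_unit_peak(pmax(t, 0), profile$k_on, profile$k_off)
  a <- switch(profile$kind,
    vehicle   = rep(a0, length(t)),
    inhibitor = a0 * (1 - profile$magnitude * b),
    activator = a0 * (1 + profile$magnitude * b)
  )
  if (any(a < 0)) {
    stop("drug profile drives calpain activity negative", call. = FALSE)
  }
  tibble::tibble(time = as.numeric(t), activity = a)
}

# Bateman onset/washout curve normalised so its maximum over t >= 0 is 1.
# k_off = 0 gives saturating onset 1 - exp(-k_on t) (no washout).
bateman_unit_peak <- function(t, k_on, k_off) {
  t <- pmax(t, 0)
  if (k_off == 0) {
    return(1 - exp(-k_on * t))
  }
  if (isTRUE(all.equal(k_on, k_off))) {
    k <- (k_on + k_off) / 2
    t_pk <- 1 / k
    raw <- t * exp(-k * t)
  } else {
    t_pk <- log(k_on / k_off) / (k_on - k_off)
    raw <- exp(-k_off * t) - exp(-k_on * t)
  }
  peak <- if (isTRUE(all.equal(k_on, k_off))) t_pk * exp(-1) else
    exp(-k_off * t_pk) - exp(-k_on * t_pk)
  raw / peak
}

# Time of the Bateman peak (h since dose); used by tests and calibration.
bateman_peak_time <- function(k_on, k_off) {
  if (k_off == 0) return(Inf)
  if (isTRUE(all.equal(k_on, k_off))) return(2 / (k_on + k_off))
  log(k_on / k_off) / (k_on - k_off)
}

#' Intact-sensor pool under a calpain-activity trace
#'
#' Integrates `dS/dt = k_syn - (k_deg + k_cl * a(t)) * S` from the pre-dose
#' steady state `S(0) = k_syn / (k_deg + k_cl * a0)` with classical
#' fixed-step fourth-order Runge-Kutta. Each interval of the requested grid is
#' subdivided so steps never exceed `max_step_s` seconds; activity is
#' interpolated linearly between grid points (or evaluated exactly when a
#' function is supplied). With constant activity the solution stays at the
#' analytic fixed point.
#'
#' @param params A [sensor_params()] object.
#' @param activity Either a numeric vector of calpain activity at `t_grid`,
#'   a tibble from [activity_trace()] (its `activity` column is used), or a
#'   function of time in hours.
#' @param t_grid Hours; strictly increasing, length >= 2.
#' @param max_step_s Maximum integration step (seconds).
#' @return Tibble with columns `time` (h), `activity`, and `sensor`
#'   (intact sensor, sensor-units).
#' @export
sensor_pool_trace <- function(params, activity, t_grid, max_step_s = 1) {
  stopifnot(inherits(params, "sensor_params"),
            is.numeric(t_grid), length(t_grid) >= 2,
            !is.unsorted(t_grid, strictly = TRUE), max_step_s > 0)
  if (params$k_deg + params$k_cl * params$a0 <= 0) {
    stop("no steady state: k_deg + k_cl * a0 must be > 0", call. = FALSE)
  }
  a_fun <- as_activity_function(activity, t_grid)
  max_step_h <- max_step_s / 3600

  s <- numeric(length(t_grid))
  s[1] <- steady_state_sensor(params)
  deriv <- function(t, S) {
    params$k_syn - (params$k_deg + params$k_cl * a_fun(t)) * S
  }
  for (i in seq_len(length(t_grid) - 1)) {
    t0 <- t_grid[i]
    t1 <- t_grid[i + 1]
    n_sub <- max(1L, ceiling((t1 - t0) / max_step_h))
    h <- (t1 - t0) / n_sub
    S <- s[i]
    tt <- t0
    for (j in seq_len(n_sub)) {
      k1 <- deriv(tt, S)
      k2 <- deriv(tt + h / 2, S + h / 2 * k1)
      k3 <- deriv(tt + h / 2, S + h / 2 * k2)
      k4 <- deriv(tt + h, S + h * k3)
      S <- S + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tt <- tt + h
    }
    s[i + 1] <- S
  }
  if (any(s <= 0)) {
    stop("sensor pool became non-positive; check kinetic parameters",
         call. = FALSE)
  }
  tibble::tibble(time = as.numeric(t_grid), activity = a_fun(t_grid), sensor = s)
}

as_activity_function <- function(activity, t_grid) {
  if (is.function(activity)) return(activity)
  if (is.data.frame(activity)) {
    stopifnot(all(c("time", "activity") %in% names(activity)))
    t_grid <- activity$time
    activity <- activity$activity
  }
  stopifnot(is.numeric(activity), length(activity) == length(t_grid))
  if (length(t_grid) == 1 || all(activity == activity[1])) {
    a0 <- activity[1]
    return(function(t) rep(a0, length(t)))
  }
  stats::approxfun(t_grid, activity, rule = 2)
}
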