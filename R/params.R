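#' Sensor kinetics parameters
#'
#' Constants of the mechanistic sensor model used by the synthetic-session
#' generator. The intact-sensor pool `S(t)` obeys
#' `dS/dt = k_syn - (k_deg + k_cl * a(t)) * S`, where `a(t)` is calpain
#' activity: the sensor is continuously synthesised, turned over at a basal
#' rate, and cleaved in proportion to calpain activity. The FRET-reporting
#' fluorescence seen by the camera is `gain * S` on top of an LED-independent
#' `ambient` background.
#'
#' @param k_syn Sensor synthesis rate (sensor-units/h). Must be > 0.
#' @param k_deg Activity-independent sensor turnover rate (1/h).
#' @param k_cl Cleavage rate per unit calpain activity (1/h per activity-unit).
#' @param a0 Basal calpain activity (activity-units, dimensionless, >= 0).
#' @param gain Fluorescence per unit intact sensor (camera counts per
#'   sensor-unit). Must be > 0.
#' @param ambient LED-independent background (camera counts).
#' @param bleach_rate Fractional gain loss per second of cumulative LED-on
#'   exposure (1/s).
#' @param noise_sd Per-frame additive Gaussian noise (camera counts).
#' @param fps Camera frame rate (frames/s).
#'
#' @return A list of class `sensor_params`.
#' @details The pre-dose steady state is `S_ss = k_syn / (k_deg + k_cl * a0)`,
#'   which must be finite and positive, so `k_deg + k_cl * a0 > 0` is required.
#' @seealso [sensor_pool_trace()], [render_session()], [simulate_cohort()]
#' @export
#' @examples
#' p <- sensor_params()
#' steady_state_sensor(p) # 100 sensor-units with the defaults
sensor_params <- function(k_syn = 60, k_deg = 0.1, k_cl = 0.5, a0 = 1,
                          gain = 1, ambient = 5, bleach_rate = 2e-6,
                          noise_sd = 2, fps = 41) {
  stopifnot(
    is.numeric(k_syn), k_syn > 0,
    is.numeric(k_deg), k_deg >= 0,
    is.numeric(k_cl), k_cl >= 0,
    is.numeric(a0), a0 >= 0,
    is.numeric(gain), gain > 0,
    is.numeric(ambient), ambient >= 0,
    is.numeric(bleach_rate), bleach_rate >= 0,
    is.numeric(noise_sd), noise_sd >= 0,
    is.numeric(fps), fps > 0
  )
  if (k_deg + k_cl * a0 <= 0) {
    stop("k_deg + k_cl * a0 must be > 0: the intact-sensor pool has no ",
         "finite steady state otherwise", call. = FALSE)
  }
  structure(
    list(k_syn = k_syn, k_deg = k_deg, k_cl = k_cl, a0 = a0, gain = gain,
         ambient = ambient, bleach_rate = bleach_rate, noise_sd = noise_sd,
         fps = fps),
    class = "sensor_params"
  )
}

#' Pre-dose steady-state intact sensor
#'
#' Closed form `k_syn / (k_deg + k_cl * a0)` for constant basal activity.
#'
#' @param params A [sensor_params()] object.
#' @param activity Calpain activity at which to evaluate the steady state
#'   (defaults to the basal activity `a0`).
#' @return Steady-state intact sensor (sensor-units).
#' @export
steady_state_sensor <- function(params, activity = params$a0) {
  denom <- params$k_deg + params$k_cl * activity
  if (any(denom <= 0)) {
    stop("no steady state: k_deg + k_cl * activity must be > 0", call. = FALSE)
  }
  params$k_syn / denom
}

#' Steady-state delta-FRET under sustained fractional inhibition
#'
#' If calpain activity is held at `a0 * (1 - f)` long enough for the sensor
#' pool to re-equilibrate, the percent change in intact sensor (and hence in
#' the FRET statistic) from its pre-dose steady state is
#' `100 * k_cl * a0 * f / (k_deg + k_cl * a0 * (1 - f))`. With `k_deg = 0`
#' this reduces to `100 * f / (1 - f)`.
#'
#' @param params A [sensor_params()] object.
#' @param f Sustained fractional inhibition of calpain activity, in `[0, 1)`.
#' @return Steady-state delta-FRET (%).
#' @export
#' @examples
#' p <- sensor_params(k_deg = 0)
#' delta_fret_steady_state(p, 0.5) # 100 * 0.5 / 0.5 = 100%
delta_fret_steady_state <- function(params, f) {
  stopifnot(is.numeric(f), all(f >= 0), all(f < 1))
  100 * params$k_cl * params$a0 * f /
    (params$k_deg + params$k_cl * params$a0 * (1 - f))
}

#' Fractional inhibition producing a target steady-state delta-FRET
#'
#' Inverse of [delta_fret_steady_state()]: the sustained fractional inhibition
#' `f` at which the re-equilibrated sensor pool sits `target_pct` percent above
#' its pre-dose steady state.
#'
#' @param params A [sensor_params()] object.
#' @param target_pct Target steady-state delta-FRET (%), > 0.
#' @return Fractional inhibition in `(0, 1)`.
#' @export
inhibition_for_steady_state <- function(params, target_pct) {
  stopifnot(is.numeric(target_pct), target_pct > 0)
  r <- target_pct / 100
  ka <- params$k_cl * params$a0
  f <- r * (params$k_deg + ka) / (ka * (1 + r))
  if (f >= 1) {
    stop("target delta-FRET is unreachable: required inhibition >= 1",
         call. = FALSE)
  }
  f
}

#' Drug effect profile
#'
#' Pharmacodynamic description of a treatment: an inhibitor scales calpain
#' activity down, an activator (an ionomycin-like calcium ionophore) scales it
#' up, and vehicle leaves it unchanged. The time course of the effect is a
#' Bateman-type onset/washout curve normalised to unit peak (see
#' [activity_trace()]).
#'
#' @param kind One of `"inhibitor"`, `"activator"`, `"vehicle"`.
#' @param magnitude Maximal fractional change in calpain activity at the
#'   effect peak: in `[0, 1)` for an inhibitor (activity cannot go negative),
#'   `>= 0` for an activator, and forced to 0 for vehicle.
#' @param k_on Effect onset rate (1/h).
#' @param k_off Effect washout rate (1/h).
#' @param label Treatment label carried into manifests and tables.
#' @param dose Dose (mg/kg), metadata only.
#' @param route Administration route (e.g. `"s.c."`, `"p.o."`, `"i.p."`),
#'   metadata only.
#' @return A list of class `drug_profile`.
#' @export
#' @examples
#' calpeptin_like <- drug_profile("inhibitor", magnitude = 0.3, dose = 2)
#' veh <- drug_profile("vehicle")
drug_profile <- function(kind = c("inhibitor", "activator", "vehicle"),
                         magnitude = 0, k_on = 12, k_off = 0.4,
                         label = NULL, dose = 0, route = "s.c.") {
  kind <- match.arg(kind)
  stopifnot(is.numeric(magnitude), length(magnitude) == 1, magnitude >= 0,
            is.numeric(k_on), k_on > 0, is.numeric(k_off), k_off >= 0)
  if (kind == "vehicle" && magnitude != 0) {
    stop("vehicle implies magnitude = 0", call. = FALSE)
  }
  if (kind == "inhibitor" && magnitude >= 1) {
    stop("inhibitor magnitude must be < 1: calpain activity would go ",
         "negative at the effect peak", call. = FALSE)
  }
  if (is.null(label)) label <- kind
  structure(
    list(kind = kind, magnitude = magnitude, k_on = k_on, k_off = k_off,
         label = label, dose = dose, route = route),
    class = "drug_profile"
  )
}

#' Recording-session schedule
#'
#' Each recording session consists of a no-excitation lead-in (settling time,
#' emitted but excluded from analysis) followed by a window of strictly
#' interleaved LED-on / LED-off frames. Sessions are run pre-treatment
#' (hour 0) and at the listed hours post-administration.
#'
#' @param hours Recording hours post-dose; must be sorted ascending and start
#'   at 0 (the pre-treatment baseline).
#' @param off_lead_s No-excitation lead-in duration (s).
#' @param interleaved_s Interleaved recording window duration (s).
#' @return A list of class `session_schedule`.
#' @export
session_schedule <- function(hours = c(0, 1, 2, 3), off_lead_s = 60,
                             interleaved_s = 60) {
  stopifnot(is.numeric(hours), length(hours) >= 1, !is.unsorted(hours, strictly = TRUE),
            hours[1] == 0, off_lead_s > 0, interleaved_s > 0)
  structure(
    list(hours = hours, off_lead_s = off_lead_s, interleaved_s = interleaved_s),
    class = "session_schedule"
  )
}

#' Simulated-cohort specification
#'
#' @param n_animals Number of animals (>= 1).
#' @param treatments List of [drug_profile()] objects; labels must be unique.
#' @param cv_k_syn,cv_gain Coefficient of variation of the per-animal
#'   lognormal jitter on sensor synthesis rate and optical gain (viral
#'   expression and coupling efficiency vary between animals).
#' @param seed Integer random seed; a fixed seed makes cohort output
#'   byte-identical across runs.
#' @param latin_square Balance treatment order across animals with a cyclic
#'   Latin square so that each treatment occupies each ordinal day position
#'   equally often.
#' @param genotypes Character vector recycled across animals (metadata only;
#'   the statistics layer pools genotypes by default).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_animals = 8,
                        treatments = list(drug_profile("vehicle"),
                                          drug_profile("inhibitor", magnitude = 0.3)),
                        cv_k_syn = 0.2, cv_gain = 0.2, seed = 1L,
                        latin_square = TRUE, genotypes = "WT") {
  stopifnot(is.numeric(n_animals), n_animals >= 1,
            length(treatments) >= 1,
            all(vapply(treatments, inherits, logical(1), "drug_profile")),
            is.numeric(cv_k_syn), cv_k_syn >= 0,
            is.numeric(cv_gain), cv_gain >= 0,
            is.numeric(seed), length(seed) == 1)
  labels <- vapply(treatments, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("treatment labels must be unique", call. = FALSE)
  }
  names(treatments) <- labels
  structure(
    list(n_animals = as.integer(n_animals), treatments = treatments,
         cv_k_syn = cv_k_syn, cv_gain = cv_gain, seed = as.integer(seed),
         latin_square = isTRUE(latin_square), genotypes = genotypes),
    class = "cohort_spec"
  )
}
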