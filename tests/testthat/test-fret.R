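test_that("session FRET is the on-mean minus the interleaved off-mean", {
  fr <- make_frames(on = 50, off = 10)
  expect_equal(compute_fret(fr)$fret, 40)
  expect_equal(compute_fret(make_frames(on = 33.3, off = 33.3))$fret, 0)

  # simulated noiseless session: gain * S = 30 above ambient, exactly
  p <- sensor_params(noise_sd = 0, bleach_rate = 0, gain = 1, ambient = 5)
  sess <- render_session(p, 30)
  expect_equal(compute_fret(sess, c(60, 120))$fret, 30)
})

test_that("compute_fret refuses windows lacking one LED state", {
  p <- sensor_params(noise_sd = 0)
  sess <- render_session(p, 30)
  expect_error(compute_fret(sess, c(0, 59)), "LED state")
})

test_that("delta-FRET follows the percent-change-from-baseline formula", {
  expect_equal(
    compute_delta_fret(tibble::tibble(hour = c(0, 1), fret = c(100, 110)))$delta_fret,
    c(0, 10)
  )
  expect_equal(
    compute_delta_fret(tibble::tibble(hour = c(0, 1), fret = c(100, 100)))$delta_fret,
    c(0, 0)
  )
  got <- compute_delta_fret(
    tibble::tibble(hour = 0:3, fret = c(80, 120, 80, 60))
  )
  expect_equal(got$delta_fret, c(0, 50, 0, -25))
})

test_that("failed baselines are errors, not sign flips", {
  expect_error(
    compute_delta_fret(tibble::tibble(hour = 0:1, fret = c(-5, 10))),
    "positive"
  )
  expect_error(
    compute_delta_fret(tibble::tibble(hour = 1:3, fret = c(1, 2, 3))),
    "hour-0"
  )
})

test_that("trapezoidal AUC matches the printed pairwise formula", {
  expect_equal(auc_trapezoid(c(0, 1), c(0, 0)), 0)
  expect_equal(auc_trapezoid(0:3, c(0, 10, 10, 10)), 25)
  expect_equal(auc_trapezoid(0:3, c(0, 50, 0, -25)), 25 + 25 - 12.5)
  # non-uniform spacing
  expect_equal(auc_trapezoid(c(0, 0.5, 3), c(0, 4, 4)), 1 + 10)
  expect_error(auc_trapezoid(1, 1), "two timepoints")
  expect_error(auc_trapezoid(c(1, 0), c(0, 1)), "increasing")
})

test_that("auc_trapezoid agrees with numerical integration of the
           piecewise-linear interpolant", {
  set.seed(101)
  for (i in 1:200) {
    y <- stats::runif(4, -50, 50)
    y[1] <- 0
    ours <- auc_trapezoid(0:3, y)
    oracle <- stats::integrate(stats::approxfun(0:3, y), 0, 3,
                               subdivisions = 2000L, rel.tol = 1e-12)$value
    expect_equal(ours, oracle, tolerance = 1e-9)
  }
})

test_that("auc_trapezoid is linear and additive over contiguous ranges", {
  set.seed(7)
  h <- c(0, 1, 2, 3)
  y <- rnorm(4); z <- rnorm(4)
  expect_equal(auc_trapezoid(h, 2 * y + 3 * z),
               2 * auc_trapezoid(h, y) + 3 * auc_trapezoid(h, z))
  expect_equal(auc_trapezoid(h, y),
               auc_trapezoid(h[1:2], y[1:2]) + auc_trapezoid(h[2:4], y[2:4]))
})

test_that("day summaries include the hour-0 zero and gate the AUC", {
  s <- tibble::tibble(hour = 0:3, delta_fret = c(0, 10, 10, 10))
  got <- summarize_day(s)
  expect_equal(got$max_delta_fret, 10)
  expect_equal(got$min_delta_fret, 0)
  expect_equal(got$auc, 25)

  neg <- summarize_day(tibble::tibble(hour = 0:3, delta_fret = c(0, -5, -10, -2)))
  expect_equal(neg$max_delta_fret, 0)
  expect_equal(neg$min_delta_fret, -10)

  gap <- summarize_day(tibble::tibble(hour = c(0, 1, 3), delta_fret = c(0, 8, 4)))
  expect_true(is.na(gap$auc))
  expect_equal(gap$max_delta_fret, 8)
})

test_that("FRET is gain-equivariant and delta-FRET gain/offset-invariant", {
  p <- sensor_params(noise_sd = 0)
  sessions <- lapply(c(0, 1, 2, 3), function(h) {
    render_session(p, 100 * (1 + 0.05 * h))
  })
  fret <- function(fs, g = 1, off = 0) {
    purrr::map_dbl(fs, function(f) {
      f$roi_intensity <- g * f$roi_intensity + off
      compute_fret(f, c(60, 120))$fret
    })
  }
  base <- fret(sessions)
  scaled <- fret(sessions, g = 3.7)
  shifted <- fret(sessions, off = 42)
  expect_equal(scaled, 3.7 * base)
  expect_equal(shifted, base)
  dfret <- function(f) {
    compute_delta_fret(tibble::tibble(hour = 0:3, fret = f))$delta_fret
  }
  expect_equal(dfret(scaled), dfret(base))
  expect_equal(dfret(shifted), dfret(base))
})

test_that("process_experiment yields one summary row per animal x treatment", {
  co <- simulate_cohort(cohort_spec(n_animals = 4, seed = 21))
  ex <- process_experiment(co)
  expect_equal(nrow(ex$summaries), 4 * 2)
  expect_equal(nrow(ex$delta_fret), 4 * 2 * 4)
  expect_true(all(ex$delta_fret$delta_fret[ex$delta_fret$hour == 0] == 0))
  expect_equal(nrow(ex$failures), 0)
  g <- glance(ex)
  expect_equal(g$n_animals, 4)
  expect_equal(g$n_sessions, 32)
  expect_identical(tidy(ex), ex$delta_fret)
})

test_that("a missing hour gaps the series and voids the AUC, nothing else", {
  co <- simulate_cohort(cohort_spec(n_animals = 2, seed = 22))
  co$manifest <- dplyr::filter(
    co$manifest,
    !(animal_id == "m01" & treatment == "inhibitor" & hour == 2)
  )
  ex <- process_experiment(co)
  s <- dplyr::filter(ex$summaries, animal_id == "m01", treatment == "inhibitor")
  expect_true(is.na(s$auc))
  expect_gt(s$max_delta_fret, 0)
  complete <- dplyr::filter(ex$summaries,
                            !(animal_id == "m01" & treatment == "inhibitor"))
  expect_true(all(!is.na(complete$auc)))
})

test_that("one failing block is reported without aborting the rest", {
  co <- simulate_cohort(cohort_spec(n_animals = 2, seed = 23))
  # wreck one baseline so delta-FRET is undefined for that block
  key <- "m01_vehicle_h0"
  co$sessions[[key]]$roi_intensity <- 0 * co$sessions[[key]]$roi_intensity
  ex <- process_experiment(co)
  expect_equal(nrow(ex$failures), 1)
  expect_equal(ex$failures$animal_id, "m01")
  expect_equal(nrow(ex$summaries), 3)
})

test_that("processing from disk equals processing in memory", {
  spec <- cohort_spec(n_animals = 2, seed = 31)
  d <- withr::local_tempdir()
  in_mem <- process_experiment(simulate_cohort(spec))
  simulate_cohort(spec, out_dir = d)
  on_disk <- process_experiment(file.path(d, "manifest.json"))
  expect_equal(as.data.frame(dplyr::arrange(on_disk$summaries, animal_id, treatment)),
               as.data.frame(dplyr::arrange(in_mem$summaries, animal_id, treatment)))
})

test_that("mean max delta-FRET rises with inhibitor magnitude (noise off)", {
  p <- sensor_params(noise_sd = 0)
  maxes <- purrr::map_dbl(c(0.1, 0.3, 0.5), function(m) {
    spec <- cohort_spec(
      n_animals = 2,
      treatments = list(drug_profile("inhibitor", magnitude = m)),
      cv_k_syn = 0, cv_gain = 0, seed = 55
    )
    ex <- process_experiment(simulate_cohort(spec, params = p))
    mean(ex$summaries$max_delta_fret)
  })
  expect_true(all(diff(maxes) > 0))
})
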