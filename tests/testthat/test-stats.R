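test_that("exclusion rule applies a strict neuron-count threshold and
           fibre placement", {
  h <- tibble::tibble(
    animal_id = c("a", "b", "c", "d"),
    eyfp_neuron_count = c(50, 150, 250, 250),
    fibre_on_target = c(TRUE, TRUE, TRUE, FALSE)
  )
  got <- exclusion_filter(h)
  expect_equal(got$excluded, c(TRUE, FALSE, FALSE, TRUE))
  expect_match(got$reason[1], "EYFP")
  expect_match(got$reason[4], "off-target")

  # exactly at the threshold is kept: the rule is a strict "<"
  at <- exclusion_filter(tibble::tibble(
    animal_id = "e", eyfp_neuron_count = 100, fibre_on_target = TRUE
  ))
  expect_false(at$excluded)
})

test_that("matched_subset keeps only animals exposed to every treatment", {
  tb <- tibble::tibble(
    animal_id = rep(c("a", "b", "c"), times = c(2, 2, 1)),
    treatment = c("veh", "drug", "veh", "drug", "veh"),
    delta_fret = 1:5
  )
  kept <- matched_subset(tb, c("veh", "drug"))
  expect_setequal(unique(kept$animal_id), c("a", "b"))
  expect_identical(matched_subset(tb[1:4, ], c("veh", "drug")), tb[1:4, ])
  expect_error(matched_subset(tb[c(1, 3), ], c("veh", "drug")), "lacks")
})

test_that("RM ANOVA recovers a pure treatment shift and flat time", {
  d <- tidyr::expand_grid(animal_id = paste0("m", 1:6), hour = 0:3,
                          treatment = c("veh", "drug"))
  set.seed(9)
  d$delta_fret <- ifelse(d$treatment == "drug", 10, 0) + rnorm(nrow(d), 0, 0.01)
  res <- rm_two_way_anova(d)
  t <- tidy(res)
  expect_lt(t$p_value[t$term == "treatment"], 1e-6)
  expect_gt(t$p_value[t$term == "hour"], 0.05)
})

test_that("constant response gives F = 0 everywhere", {
  d <- tidyr::expand_grid(animal_id = paste0("m", 1:4), hour = 0:3,
                          treatment = c("a", "b"))
  d$delta_fret <- 5
  res <- rm_two_way_anova(d)
  expect_true(all(is.na(tidy(res)$statistic) | tidy(res)$statistic == 0))
})

test_that("RM ANOVA F terms match a brute-force sums-of-squares
           decomposition", {
  set.seed(31)
  n_id <- 5; hours <- 0:3; trts <- c("veh", "drug")
  d <- tidyr::expand_grid(animal_id = paste0("m", 1:n_id), hour = hours,
                          treatment = trts)
  cell_mean <- with(d, 2 * hour + ifelse(treatment == "drug", 5, 0) +
                      0.5 * hour * (treatment == "drug"))
  d$delta_fret <- cell_mean + rnorm(nrow(d), 0, 1)

  # brute force: classical within-subject decomposition from cell means
  y <- d$delta_fret
  a <- factor(d$hour); b <- factor(d$treatment); s <- factor(d$animal_id)
  I <- nlevels(a); J <- nlevels(b); n <- nlevels(s)
  gm <- mean(y)
  m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_s <- tapply(y, s, mean)
  m_ab <- tapply(y, list(a, b), mean)
  m_as <- tapply(y, list(a, s), mean)
  m_bs <- tapply(y, list(b, s), mean)
  ss_a <- J * n * sum((m_a - gm)^2)
  ss_b <- I * n * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, J)) -
                      outer(rep(1, I), m_b) + gm)^2)
  ss_as <- J * sum((m_as - outer(m_a, rep(1, n)) -
                      outer(rep(1, I), m_s) + gm)^2)
  ss_bs <- I * sum((m_bs - outer(m_b, rep(1, n)) -
                      outer(rep(1, J), m_s) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_s <- I * J * sum((m_s - gm)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs
  f_a <- (ss_a / (I - 1)) / (ss_as / ((I - 1) * (n - 1)))
  f_b <- (ss_b / (J - 1)) / (ss_bs / ((J - 1) * (n - 1)))
  f_ab <- (ss_ab / ((I - 1) * (J - 1))) /
    (ss_abs / ((I - 1) * (J - 1) * (n - 1)))

  t <- tidy(rm_two_way_anova(d))
  expect_equal(t$statistic[t$term == "hour"], f_a, tolerance = 1e-10)
  expect_equal(t$statistic[t$term == "treatment"], f_b, tolerance = 1e-10)
  expect_equal(t$statistic[t$term == "hour:treatment"], f_ab,
               tolerance = 1e-10)
  expect_equal(t$df_num, c(I - 1, J - 1, (I - 1) * (J - 1)))
  expect_equal(t$df_den, c((I - 1) * (n - 1), (J - 1) * (n - 1),
                           (I - 1) * (J - 1) * (n - 1)))
})

test_that("missing cells trigger the mixed-effects fallback", {
  d <- tidyr::expand_grid(animal_id = paste0("m", 1:6), hour = 0:3,
                          treatment = c("veh", "drug"))
  set.seed(13)
  d$delta_fret <- ifelse(d$treatment == "drug", 8, 0) + rnorm(nrow(d))
  d_miss <- d[-c(3, 17), ]
  expect_error(rm_two_way_anova(d_miss, allow_missing = FALSE), "mixed")
  res <- rm_two_way_anova(d_miss, allow_missing = TRUE)
  expect_match(res$method, "mixed")
  t <- tidy(res)
  expect_lt(t$p_value[t$term == "treatment"], 1e-4)
  expect_true(all(t$df_den > 0))
})

test_that("complete-data aov and the mixed model agree in the balanced
           compound-symmetric limit", {
  # Construct a response whose error decomposes into the within-subject
  # strata with exactly equal mean squares (the empirical compound-symmetric
  # limit): the classical RM denominator for each effect and the pooled
  # mixed-model residual then coincide, so the F ratios must match.
  set.seed(77)
  ids <- paste0("m", 1:8); hours <- 0:3; trts <- c("veh", "drug")
  d <- tidyr::expand_grid(animal_id = ids, hour = hours, treatment = trts)
  a <- factor(d$hour); b <- factor(d$treatment); s <- factor(d$animal_id)
  eps <- rnorm(nrow(d))
  # decompose eps into the within-subject error strata and rescale each to
  # unit mean square
  fit0 <- stats::aov(eps ~ a * b + Error(s / (a * b)))
  pr <- stats::proj(fit0)
  comp_as <- as.numeric(pr[["s:a"]][, "Residuals"])
  comp_bs <- as.numeric(pr[["s:b"]][, "Residuals"])
  comp_abs <- as.numeric(pr[["s:a:b"]][, "Residuals"])
  unit_ms <- function(x, df) x / sqrt(sum(x^2) / df)
  n <- length(ids); I <- length(hours); J <- length(trts)
  err <- unit_ms(comp_as, (I - 1) * (n - 1)) +
    unit_ms(comp_bs, (J - 1) * (n - 1)) +
    unit_ms(comp_abs, (I - 1) * (J - 1) * (n - 1))
  subj_eff <- rnorm(n, 0, 2)[as.integer(s)]
  d$delta_fret <- subj_eff + 2 * (d$treatment == "drug") + 0.3 * d$hour + err

  f_aov <- tidy(rm_two_way_anova(d))
  # force the mixed route on the same complete data
  fit_mix <- lmerTest::lmer(
    delta_fret ~ factor(hour) * treatment + (1 | animal_id), data = d,
    REML = TRUE
  )
  an <- stats::anova(fit_mix, type = 3, ddf = "Satterthwaite")
  f_mix <- an$`F value`
  expect_equal(f_mix[1], f_aov$statistic[f_aov$term == "hour"],
               tolerance = 0.01)
  expect_equal(f_mix[2], f_aov$statistic[f_aov$term == "treatment"],
               tolerance = 0.01)
  expect_equal(f_mix[3], f_aov$statistic[f_aov$term == "hour:treatment"],
               tolerance = 0.01)
})

test_that("one-way ANOVA with identical groups gives F = 0, p = 1", {
  tb <- tibble::tibble(value = rep(c(1, 2, 3), 2),
                       group = rep(c("A", "B"), each = 3))
  t <- tidy(one_way_anova_tukey(tb))
  expect_equal(t$statistic, 0)
  expect_equal(t$p_value, 1)
})

test_that("Tukey separates clearly shifted groups and never undercuts the
           raw p", {
  set.seed(5)
  tb <- tibble::tibble(
    value = c(rnorm(6, 0, 0.01), rnorm(6, 10, 0.01), rnorm(6, 0.01, 0.01)),
    group = rep(c("A", "B", "C"), each = 6)
  )
  res <- one_way_anova_tukey(tb)
  ph <- res$posthoc
  expect_lt(ph$p_adj[ph$comparison == "B-A"], 1e-6)
  expect_true(all(ph$p_adj >= ph$p_raw - 1e-12))
})

test_that("one-way ANOVA F matches the brute-force between/within ratio", {
  set.seed(17)
  tb <- tibble::tibble(value = rnorm(15, rep(c(0, 1, 3), each = 5)),
                       group = rep(c("A", "B", "C"), each = 5))
  y <- tb$value; g <- tb$group
  gm <- mean(y)
  ss_b <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ss_w <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ss_b / 2) / (ss_w / 12)
  t <- tidy(one_way_anova_tukey(tb))
  expect_equal(t$statistic, f_oracle, tolerance = 1e-10)
})

test_that("groups of fewer than two values are rejected", {
  tb <- tibble::tibble(value = c(1, 2, 3), group = c("A", "A", "B"))
  expect_error(one_way_anova_tukey(tb), "at least two values")
})

test_that("paired t matches mean(d)/(sd(d)/sqrt(n)) and zero variance is an
           error", {
  x <- c(2, 2.1, 1.9, 2.0); y <- c(1, 1.0, 1.0, 1.0)
  d <- x - y
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  got <- tidy(fret_t_test(x, y, paired = TRUE))
  expect_equal(got$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(got$df_den, 3)
  expect_error(fret_t_test(x, x, paired = TRUE), "zero variance")
})

test_that("unpaired t under the null is unremarkable", {
  set.seed(2)
  x <- rnorm(5); y <- rnorm(5)
  got <- tidy(fret_t_test(x, y))
  expect_lt(abs(got$statistic), 3)
  expect_gt(got$p_value, 0.01)
})

test_that("Pearson correlation handles exact linear relations and matches the
           covariance formula", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(4)
  a <- rnorm(10); b <- rnorm(10)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  got <- pearson_correlation(a, b)
  expect_equal(got$r, r_oracle, tolerance = 1e-10)
  expect_equal(got$r_squared, r_oracle^2, tolerance = 1e-10)
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "constant")
})

test_that("stat results tidy and glance coherently", {
  set.seed(6)
  tb <- tibble::tibble(value = rnorm(12), group = rep(c("A", "B", "C"), 4))
  res <- one_way_anova_tukey(tb)
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$min_p_value, min(tidy(res)$p_value))
})
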