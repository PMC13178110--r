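#' Histology-based animal exclusion
#'
#' Applies the study's exclusion rule: animals with fewer than
#' `neuron_threshold` sensor-expressing (EYFP-positive) neurons, or with
#' off-target fibre placement, are excluded from analysis. The threshold is a
#' strict `<`, so an animal with exactly the threshold count is kept.
#'
#' @param histology Tibble with columns `animal_id`, `eyfp_neuron_count`,
#'   `fibre_on_target` (logical).
#' @param neuron_threshold Minimum EYFP+ neuron count (strict `<` excludes).
#' @return The input with logical `excluded` and character `reason` columns.
#' @export
#' @examples
#' h <- tibble::tibble(animal_id = c("a", "b"), eyfp_neuron_count = c(50, 150),
#'                     fibre_on_target = c(TRUE, TRUE))
#' exclusion_filter(h)
exclusion_filter <- function(histology, neuron_threshold = 100) {
  stopifnot(is.data.frame(histology),
            all(c("animal_id", "eyfp_neuron_count", "fibre_on_target")
                %in% names(histology)),
            all(histology$eyfp_neuron_count >= 0))
  few <- histology$eyfp_neuron_count < neuron_threshold
  off <- !histology$fibre_on_target
  reason <- dplyr::case_when(
    few & off ~ sprintf("<%d EYFP+ neurons; off-target fibre", neuron_threshold),
    few ~ sprintf("<%d EYFP+ neurons", neuron_threshold),
    off ~ "off-target fibre placement",
    TRUE ~ NA_character_
  )
  dplyr::mutate(histology, excluded = few | off, reason = reason)
}

#' Restrict a cohort table to animals with matched data
#'
#' Keeps only animals exposed to every named treatment, mirroring the
#' matched-data inclusion rule: dose-comparison analyses use only animals
#' that received all doses of the compound.
#'
#' @param table Long cohort tibble with `animal_id` and `treatment` columns.
#' @param treatments Treatment labels that must all be present per animal;
#'   defaults to every treatment in the table.
#' @return The filtered tibble.
#' @export
matched_subset <- function(table, treatments = unique(table$treatment)) {
  stopifnot(is.data.frame(table),
            all(c("animal_id", "treatment") %in% names(table)))
  per_animal <- table |>
    dplyr::filter(.data$treatment %in% treatments) |>
    dplyr::distinct(.data$animal_id, .data$treatment)
  complete <- per_animal |>
    dplyr::count(.data$animal_id) |>
    dplyr::filter(.data$n == length(treatments)) |>
    dplyr::pull(.data$animal_id)
  if (length(complete) == 0) {
    missing <- per_animal |>
      dplyr::group_by(.data$animal_id) |>
      dplyr::summarise(
        lacking = paste(setdiff(treatments, .data$treatment), collapse = ", "),
        .groups = "drop"
      )
    stop("no animal has complete data across the requested treatments; ",
         paste(sprintf("%s lacks [%s]", missing$animal_id, missing$lacking),
               collapse = "; "), call. = FALSE)
  }
  dplyr::filter(table, .data$animal_id %in% complete)
}

new_stat_result <- function(test, terms, posthoc = NULL, n = NA_integer_,
                            method = NA_character_) {
  structure(
    list(test = test, terms = terms, posthoc = posthoc, n = n,
         method = method),
    class = "photofret_stat"
  )
}

#' @export
print.photofret_stat <- function(x, ...) {
  cat("<photofret_stat>", x$test,
      if (!is.na(x$method)) paste0("(", x$method, ")"), "\n")
  print(x$terms)
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Tidy a statistical result
#'
#' @param x A `photofret_stat`.
#' @param ... Unused.
#' @return The per-term tibble (term, statistic, dfs, p-value).
#' @method tidy photofret_stat
#' @export
tidy.photofret_stat <- function(x, ...) x$terms

#' One-row overview of a statistical result
#'
#' @param x A `photofret_stat`.
#' @param ... Unused.
#' @return One-row tibble: test, method, minimum term p-value, n.
#' @method glance photofret_stat
#' @export
glance.photofret_stat <- function(x, ...) {
  tibble::tibble(test = x$test, method = x$method,
                 min_p_value = min(x$terms$p_value), n = x$n)
}

#' Two-way repeated-measures ANOVA on delta-FRET (time x treatment)
#'
#' With complete data this is the classical repeated-measures decomposition:
#' both factors are within-subject (every animal contributes every hour of
#' every treatment day), so each effect is tested against its own
#' subject-by-effect interaction stratum via `aov()` with `Error()` terms.
#' With missing cells and `allow_missing = TRUE` the analysis falls back to a
#' REML mixed model with a random intercept per animal (`lmerTest`), the
#' minimal faithful analogue of a mixed-effects two-way ANOVA, with
#' Satterthwaite denominator degrees of freedom. No sphericity correction is
#' applied by default.
#'
#' @param table Long cohort tibble.
#' @param dv,within,between,subject Column names (strings) of the response,
#'   the repeated time factor, the treatment factor, and the animal
#'   identifier.
#' @param allow_missing Fall back to the mixed model when cells are missing;
#'   when `FALSE`, missing cells are an error directing to the fallback.
#' @return A `photofret_stat` with F, numerator/denominator dfs and p per
#'   term (`treatment`, `hour`, `hour:treatment`), plus the fitted model in
#'   `$fit`.
#' @export
rm_two_way_anova <- function(table, dv = "delta_fret", within = "hour",
                             between = "treatment", subject = "animal_id",
                             allow_missing = TRUE) {
  stopifnot(is.data.frame(table),
            all(c(dv, within, between, subject) %in% names(table)))
  d <- tibble::tibble(
    y = table[[dv]],
    time = factor(table[[within]]),
    trt = factor(table[[between]]),
    id = factor(table[[subject]])
  )
  if (nlevels(d$time) < 2 || nlevels(d$trt) < 2) {
    stop("each factor needs at least two levels", call. = FALSE)
  }
  term_names <- c(within, between, paste(within, between, sep = ":"))
  if (stats::var(d$y) == 0) {
    # identical response in every cell: all effect sums of squares are zero
    terms <- tibble::tibble(term = term_names, df_num = NA_real_,
                            df_den = NA_real_, statistic = 0, p_value = 1)
    return(new_stat_result("two-way RM ANOVA (time x treatment)", terms,
                           n = nlevels(d$id), method = "degenerate (zero variance)"))
  }
  cells <- table(d$id, d$time, d$trt)
  complete <- all(cells == 1)
  if (!complete && !allow_missing) {
    stop("missing or duplicated cells; use allow_missing = TRUE for the ",
         "mixed-effects fallback", call. = FALSE)
  }

  if (complete) {
    fit <- stats::aov(y ~ time * trt + Error(id / (time * trt)), data = d)
    sm <- summary(fit)
    pull_term <- function(stratum, term) {
      tab <- sm[[stratum]][[1]]
      rn <- trimws(rownames(tab))
      i <- match(term, rn)
      res <- match("Residuals", rn)
      tibble::tibble(
        term = term,
        df_num = tab[i, "Df"], df_den = tab[res, "Df"],
        statistic = tab[i, "F value"], p_value = tab[i, "Pr(>F)"]
      )
    }
    terms <- dplyr::bind_rows(
      pull_term("Error: id:time", "time"),
      pull_term("Error: id:trt", "trt"),
      pull_term("Error: id:time:trt", "time:trt")
    )
    terms$term <- c(within, between, paste(within, between, sep = ":"))
    method <- "repeated-measures ANOVA (aov, Error strata)"
  } else {
    fit <- lmerTest::lmer(y ~ time * trt + (1 | id), data = d, REML = TRUE)
    an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    terms <- tibble::tibble(
      term = c(within, between, paste(within, between, sep = ":")),
      df_num = an$NumDF, df_den = an$DenDF,
      statistic = an$`F value`, p_value = an$`Pr(>F)`
    )
    method <- "mixed-effects model (REML, random intercept, Satterthwaite df)"
  }
  out <- new_stat_result("two-way RM ANOVA (time x treatment)", terms,
                         n = nlevels(d$id), method = method)
  out$fit <- fit
  out
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Omnibus F across groups, followed by Tukey honestly-significant-difference
#' adjusted pairwise comparisons; raw (unadjusted) pairwise p-values from the
#' same pooled-variance statistics are reported alongside for reference.
#'
#' @param table Tibble in long format.
#' @param value,group Column names (strings) of the response and the grouping
#'   factor.
#' @return A `photofret_stat`; `$posthoc` holds the pairwise table
#'   (`comparison`, `estimate`, `p_raw`, `p_adj`).
#' @export
one_way_anova_tukey <- function(table, value = "value", group = "group") {
  stopifnot(is.data.frame(table), all(c(value, group) %in% names(table)))
  d <- tibble::tibble(y = table[[value]], g = factor(table[[group]]))
  if (nlevels(d$g) < 2) stop("at least two groups required", call. = FALSE)
  sizes <- table(d$g)
  if (any(sizes < 2)) {
    stop("every group needs at least two values; offending group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(y ~ g, data = d)
  tab <- summary(fit)[[1]]
  terms <- tibble::tibble(
    term = group,
    df_num = tab["g", "Df"], df_den = tab["Residuals", "Df"],
    statistic = tab["g", "F value"], p_value = tab["g", "Pr(>F)"]
  )
  posthoc <- NULL
  if (nlevels(d$g) > 2) {
    tk <- stats::TukeyHSD(fit)$g
    mse <- tab["Residuals", "Mean Sq"]
    df_res <- tab["Residuals", "Df"]
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    se <- vapply(pairs, function(p) {
      sqrt(mse * (1 / sizes[[p[1]]] + 1 / sizes[[p[2]]]))
    }, numeric(1))
    t_stat <- tk[, "diff"] / se
    posthoc <- tibble::tibble(
      comparison = rownames(tk),
      estimate = tk[, "diff"],
      p_raw = 2 * stats::pt(-abs(t_stat), df_res),
      p_adj = tk[, "p adj"]
    )
  }
  new_stat_result("one-way ANOVA + Tukey HSD", terms, posthoc = posthoc,
                  n = nrow(d), method = "aov + TukeyHSD")
}

#' Paired or unpaired t-test
#'
#' Two-sided Student's t-test; Welch's correction is used for the unpaired
#' case. Zero variance in the relevant quantity (the paired differences, or
#' both samples) is an error rather than a silent `t = 0`: a degenerate
#' input usually means a broken upstream table.
#'
#' @param x,y Numeric vectors; equal length required when `paired`.
#' @param paired Paired test on `x - y`?
#' @return A `photofret_stat` with t, df and the two-sided p.
#' @export
fret_t_test <- function(x, y, paired = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (paired) {
    if (length(x) != length(y)) {
      stop("paired test requires equal-length samples", call. = FALSE)
    }
    if (length(x) < 2) stop("need at least two pairs", call. = FALSE)
    if (stats::sd(x - y) == 0) {
      stop("zero variance in paired differences: t is undefined",
           call. = FALSE)
    }
  } else {
    if (length(x) < 2 || length(y) < 2) {
      stop("need at least two values per sample", call. = FALSE)
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      stop("zero variance in both samples: t is undefined", call. = FALSE)
    }
  }
  ht <- stats::t.test(x, y, paired = paired)
  terms <- tibble::tibble(
    term = if (paired) "paired difference" else "group difference",
    df_num = 1, df_den = unname(ht$parameter),
    statistic = unname(ht$statistic), p_value = ht$p.value
  )
  new_stat_result(if (paired) "paired t-test" else "unpaired t-test (Welch)",
                  terms, n = length(x), method = ht$method)
}

#' Pearson correlation
#'
#' Used for relationships such as transduced-neuron count at euthanasia
#' versus days since transduction or number of test sessions.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, non-constant.
#' @return One-row tibble: `r`, `r_squared`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must match in length", call. = FALSE)
  if (length(x) < 3) stop("need at least three pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ht$estimate)
  tibble::tibble(r = r, r_squared = r^2, p_value = ht$p.value, n = length(x))
}
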