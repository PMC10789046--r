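# Surveillance performance metrics: per-trigger PPV, cohort rates,
# three-method comparison, distributions, proportion intervals, and the
# ADE risk-factor regression.
#
# All rates are computed on exact integer counts; percentages are rounded
# half-up to two decimals only at rendering.

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

pct <- function(x) round_half_up(100 * x, 2)

#' Per-trigger positive predictive value
#'
#' One row per registry trigger (including silent ones): the number of
#' positive hits, the number of those hits linked to an adjudicated ADE, and
#' PPV = ADE hits / positive hits (undefined, `NA`, when a trigger never
#' fired; rendered `"-"`).
#'
#' @param hits Hit table from [screen_cohort()].
#' @param ades ADE table from [consolidate_ades()].
#' @param registry The registry that produced the hits.
#' @return Tibble: `trigger_id`, `module`, `positive_count`,
#'   `ade_hit_count`, `ppv` (fraction), `ppv_pct` (rendered percentage).
#' @export
trigger_performance <- function(hits, ades, registry) {
  ids <- vapply(registry$triggers, `[[`, "", "trigger_id")
  unknown <- setdiff(unique(hits$trigger_id), ids)
  if (length(unknown)) {
    stop("hit table references trigger absent from registry: ", unknown[[1]],
         call. = FALSE)
  }
  flagged <- ade_flagged_hits(hits, ades)
  pos <- vapply(ids, function(id) sum(hits$trigger_id == id), 0L)
  adeh <- vapply(ids, function(id) sum(flagged[hits$trigger_id == id]), 0L)
  ppv <- ifelse(pos > 0, adeh / pos, NA_real_)
  tibble::tibble(
    trigger_id = ids,
    module = vapply(registry$triggers, `[[`, "", "module"),
    positive_count = pos,
    ade_hit_count = adeh,
    ppv = ppv,
    ppv_pct = pct(ppv)
  )
}

#' Cohort-level screening summary
#'
#' The headline surveillance numbers for one registry run: positive-record
#' rate, hits per positive record, overall PPV (ADE-linked hits over all
#' hits), ADE incidence per 100 admissions and per 1000 patient-days, and
#' the count of triggers that fired.
#'
#' @param cohort The screened cohort (denominators).
#' @param hits Hit table.
#' @param ades ADE table.
#' @param registry Registry (for the trigger denominator).
#' @return A one-row tibble.
#' @export
cohort_summary <- function(cohort, hits, ades, registry) {
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  n <- length(cohort)
  patient_days <- sum(vapply(cohort, length_of_stay, 0))
  flagged <- ade_flagged_hits(hits, ades)
  n_pos_rec <- length(unique(hits$record_id))
  total_hits <- nrow(hits)
  n_ades <- nrow(ades)
  ids <- vapply(registry$triggers, `[[`, "", "trigger_id")
  n_trig_pos <- length(intersect(ids, unique(hits$trigger_id)))
  tibble::tibble(
    n_records = n,
    n_positive_records = n_pos_rec,
    total_hits = total_hits,
    total_ade_flagged_hits = sum(flagged),
    n_ades = n_ades,
    total_patient_days = patient_days,
    positive_record_rate = n_pos_rec / n,
    hits_per_positive_record = if (n_pos_rec > 0) total_hits / n_pos_rec else NA_real_,
    overall_ppv = if (total_hits > 0) sum(flagged) / total_hits else NA_real_,
    ades_per_100_admissions = 100 * n_ades / n,
    ades_per_1000_patient_days = 1000 * n_ades / patient_days,
    n_triggers_positive = n_trig_pos,
    n_triggers_total = length(ids)
  )
}

#' Three-method detection comparison
#'
#' Compares ADE detection by the obstetric triggers, the GTT comparator and
#' the spontaneous reporting system over the same adjudicated ADE
#' denominator.
#'
#' @param ades ADE table with detection flags.
#' @param n_records,patient_days Cohort denominators for the incidence
#'   columns.
#' @return Tibble with one row per method: `detected`, `not_detected`,
#'   `detection_rate`, `ades_per_100`, `ades_per_1000_pd`.
#' @export
method_comparison <- function(ades, n_records, patient_days) {
  total_ades <- nrow(ades)
  det <- c(obstetric = sum(ades$detected_obstetric),
           gtt = sum(ades$detected_gtt),
           srs = sum(ades$detected_srs))
  tibble::tibble(
    method = names(det),
    detected = as.integer(det),
    not_detected = total_ades - as.integer(det),
    n_ades = total_ades,
    detection_rate = if (total_ades > 0) unname(det) / total_ades else
      rep(NA_real_, 3),
    ades_per_100 = 100 * unname(det) / n_records,
    ades_per_1000_pd = 1000 * unname(det) / patient_days
  )
}

#' Confidence interval for a proportion
#'
#' Default is the Wald (normal approximation) interval
#' `p +/- z * sqrt(p(1-p)/n)`; the Wilson score interval is available with
#' `method = "wilson"`. Wald bounds are truncated to `[0, 1]` only on
#' request; Wilson bounds lie in `[0, 1]` by construction.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n > 0`.
#' @param level Coverage level (default 0.95).
#' @param method `"wald"` or `"wilson"`.
#' @param truncate Truncate Wald bounds to `[0, 1]`.
#' @return Tibble: `estimate`, `lower`, `upper`, `method`, `level`.
#' @export
proportion_ci <- function(successes, n, level = 0.95,
                          method = c("wald", "wilson"), truncate = FALSE) {
  method <- match.arg(method)
  if (n <= 0) stop("proportion_ci: n must be positive", call. = FALSE)
  if (successes < 0 || successes > n) {
    stop("proportion_ci: successes must lie in [0, n]", call. = FALSE)
  }
  p <- successes / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    se <- sqrt(p * (1 - p) / n)
    lo <- p - z * se
    hi <- p + z * se
    if (truncate) {
      lo <- max(0, lo); hi <- min(1, hi)
    }
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- centre - half
    hi <- centre + half
  }
  tibble::tibble(estimate = p, lower = lo, upper = hi, method = method,
                 level = level)
}

#' Severity and organ-class distributions
#'
#' @param ades ADE table.
#' @return List of two tibbles, `severity` (by CTCAE grade) and
#'   `organ_class`, each with counts and percentages over the ADE total.
#' @export
distribution_summary <- function(ades) {
  if (!nrow(ades)) stop("distribution_summary: no ADEs", call. = FALSE)
  n <- nrow(ades)
  sev <- tibble::tibble(grade = 1:5,
                        count = vapply(1:5, function(g) sum(ades$grade == g), 0L))
  sev$percent <- pct(sev$count / n)
  org_counts <- sort(table(ades$organ_class), decreasing = TRUE)
  org <- tibble::tibble(organ_class = names(org_counts),
                        count = as.integer(org_counts))
  org$percent <- pct(org$count / n)
  list(severity = sev, organ_class = org)
}

#' Logistic regression of ADE risk factors
#'
#' Fits a binary-outcome logistic model (maximum likelihood via
#' [stats::glm()]) of "record has at least one adjudicated ADE" on
#' record-level covariates: age, length of stay (days), number of drugs,
#' number of antibacterial drugs, number of injectable drugs, and
#' cesarean/vaginal delivery indicators. Confidence intervals are Wald on
#' the log-odds scale.
#'
#' @param cohort Patient cohort.
#' @param ades ADE table (defines the outcome).
#' @param covariates Subset of `age`, `length_of_stay`, `n_drugs`,
#'   `n_antibacterials`, `n_injections`, `cesarean`, `vaginal`.
#' @param level CI level.
#' @return Tibble: `term`, `estimate` (log-odds), `or`, `or_lower`,
#'   `or_upper`, `p_value`, plus attribute `"model"` with the glm fit.
#' @export
fit_risk_model <- function(cohort, ades,
                           covariates = c("age", "length_of_stay", "n_drugs",
                                          "n_antibacterials", "n_injections",
                                          "cesarean", "vaginal"),
                           level = 0.95) {
  allowed <- c("age", "length_of_stay", "n_drugs", "n_antibacterials",
               "n_injections", "cesarean", "vaginal")
  bad <- setdiff(covariates, allowed)
  if (length(bad)) stop("unknown covariate: ", bad[[1]], call. = FALSE)
  ade_recs <- unique(ades$record_id)
  df <- data.frame(
    outcome = vapply(cohort, function(r) r$record_id %in% ade_recs, FALSE),
    age = vapply(cohort, `[[`, 0, "age"),
    length_of_stay = vapply(cohort, length_of_stay, 0),
    n_drugs = vapply(cohort, function(r) length(r$exposures), 0L),
    n_antibacterials = vapply(cohort, function(r) {
      sum(vapply(r$exposures, function(e) "antibiotic" %in% e$drug_classes, FALSE))
    }, 0L),
    n_injections = vapply(cohort, function(r) {
      sum(vapply(r$exposures, function(e) e$route %in% c("IV", "IM"), FALSE))
    }, 0L),
    cesarean = vapply(cohort, function(r) r$delivery_mode == "cesarean", FALSE),
    vaginal = vapply(cohort, function(r) r$delivery_mode == "vaginal", FALSE)
  )
  for (cv in covariates) {
    if (stats::var(as.numeric(df[[cv]])) == 0) {
      stop("covariate constant across cohort: ", cv, call. = FALSE)
    }
  }
  form <- stats::as.formula(paste("outcome ~", paste(covariates, collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = df)
  fitted_p <- stats::fitted(fit)
  if (!fit$converged ||
      (any(fitted_p > 1 - 1e-10) || any(fitted_p < 1e-10)) &&
      any(abs(stats::coef(fit)[-1]) > 10)) {
    stop(paste("risk model shows complete or quasi-complete separation;",
               "odds ratios are not estimable — reduce covariates or pool",
               "categories"), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- sm[-1, "Estimate"]
  se <- sm[-1, "Std. Error"]
  out <- tibble::tibble(
    term = rownames(sm)[-1],
    estimate = unname(est),
    or = exp(unname(est)),
    or_lower = exp(unname(est - z * se)),
    or_upper = exp(unname(est + z * se)),
    p_value = unname(sm[-1, "Pr(>|z|)"])
  )
  # drop "TRUE" suffixes from logical covariates
  out$term <- sub("TRUE$", "", out$term)
  attr(out, "model") <- fit
  out
}
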